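# Compact attention-encoder classifier: learned word embeddings plus
# positional embeddings, a stack of multi-head self-attention blocks with
# residual connections, masked mean pooling and sigmoid heads. Stands in
# for a large pretrained transformer while honouring the same training
# contract (truncation at 512 tokens, batch 32, 8 epochs, selection by
# validation accuracy). Backpropagation is hand-written, which exposes the
# gradient of the loss with respect to every post-softmax attention weight
# — the quantity attention-gradient attribution (AGRAD) needs.

#' Attention encoder configuration
#'
#' @param n_layers Encoder layers (default 2).
#' @param n_heads Attention heads per layer (default 4; must divide
#'   `model_dim`).
#' @param model_dim Embedding/hidden width (default 128).
#' @param max_tokens Truncation length (default 512 words).
#' @param min_count Minimum training-corpus frequency for a vocabulary
#'   entry (default 1).
#' @param seed Initialisation seed.
#' @return An `encoder_config`.
#' @export
encoder_config <- function(n_layers = 2L, n_heads = 4L, model_dim = 128L,
                           max_tokens = 512L, min_count = 1L, seed = 1L) {
  stopifnot(model_dim %% n_heads == 0L, n_layers >= 1L, max_tokens >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 model_dim = as.integer(model_dim),
                 max_tokens = as.integer(max_tokens),
                 min_count = as.integer(min_count),
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Build a word-level vocabulary from training texts
#'
#' @param texts Character vector.
#' @param cfg An `encoder_config`.
#' @return Character vector of vocabulary words ("<unk>" first).
#' @export
build_vocab <- function(texts, cfg = encoder_config()) {
  toks <- unlist(lapply(texts, function(t) tolower(tokenize_words(t))))
  tab <- table(toks)
  keep <- names(tab)[tab >= cfg$min_count]
  c("<unk>", sort(keep))
}

.tc_encode_ids <- function(text, vocab, max_tokens) {
  toks <- tolower(tokenize_words(text))
  if (length(toks) > max_tokens) toks <- toks[seq_len(max_tokens)]
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- 1L  # <unk>
  list(ids = ids, tokens = toks)
}

.tc_encoder_init <- function(cfg, vocab_size, tasks = "primary") {
  .tc_with_seed(cfg$seed, 31L, function() {
    d <- cfg$model_dim
    # shared encoder parameters first so they are identical across task
    # sets with the same seed; task heads consume the RNG last
    E <- .tc_glorot(vocab_size, d) * 0.5
    P <- .tc_glorot(cfg$max_tokens, d) * 0.1
    layers <- lapply(seq_len(cfg$n_layers), function(l) {
      list(Wq = .tc_glorot(d, d), Wk = .tc_glorot(d, d),
           Wv = .tc_glorot(d, d), Wo = .tc_glorot(d, d))
    })
    heads <- list()
    if ("primary" %in% tasks) heads$primary <- list(W = .tc_glorot(d, 1L),
                                                    b = numeric(1))
    if ("emotion" %in% tasks) heads$emotion <- list(W = .tc_glorot(d, 6L),
                                                    b = numeric(6))
    if ("personality" %in% tasks)
      heads$personality <- list(W = .tc_glorot(d, 4L), b = numeric(4))
    list(E = E, P = P, layers = layers, heads = heads)
  })
}

# forward for ONE document. Returns pooled vector, caches and attention.
# alpha_override: optional list(layer=, alpha=H x T x T array) replacing
# the post-softmax attention of one layer (used by the finite-difference
# oracle for AGRAD).
.tc_encoder_forward_doc <- function(params, cfg, ids, alpha_override = NULL) {
  Tt <- length(ids)
  d <- cfg$model_dim; Hh <- cfg$n_heads; dk <- d %/% Hh
  X <- params$E[ids, , drop = FALSE] + params$P[seq_len(Tt), , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    par <- params$layers[[l]]
    Q <- X %*% par$Wq; K <- X %*% par$Wk; V <- X %*% par$Wv
    alpha <- array(0, dim = c(Hh, Tt, Tt))
    O <- matrix(0, Tt, d)
    for (h in seq_len(Hh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dk)
      S <- S - apply(S, 1L, max)
      Ea <- exp(S)
      a <- Ea / rowSums(Ea)
      if (!is.null(alpha_override) && alpha_override$layer == l) {
        a <- matrix(alpha_override$alpha[h, , ], Tt, Tt)
      }
      alpha[h, , ] <- a
      O[, cols] <- a %*% V[, cols, drop = FALSE]
    }
    out <- O %*% par$Wo
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, alpha = alpha, O = O)
    X <- X + out
  }
  u <- colMeans(X)
  list(u = u, X = X, caches = caches, Tt = Tt)
}

# backward for ONE document given du (grad wrt pooled vector).
# Accumulates into the environment-provided gradient list; returns dalpha
# per layer (for AGRAD).
.tc_encoder_backward_doc <- function(params, cfg, ids, fwd, du, grads) {
  Tt <- fwd$Tt
  d <- cfg$model_dim; Hh <- cfg$n_heads; dk <- d %/% Hh
  dX <- matrix(rep(du / Tt, each = Tt), Tt, d)  # mean pooling
  dalpha_layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    cc <- fwd$caches[[l]]
    par <- params$layers[[l]]
    # X_out = X + O Wo
    dOut <- dX
    dO <- dOut %*% t(par$Wo)
    grads$layers[[l]]$Wo <- grads$layers[[l]]$Wo + t(cc$O) %*% dOut
    dQ <- matrix(0, Tt, d); dK <- matrix(0, Tt, d); dV <- matrix(0, Tt, d)
    dalpha <- array(0, dim = c(Hh, Tt, Tt))
    for (h in seq_len(Hh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      a <- matrix(cc$alpha[h, , ], Tt, Tt)
      dOh <- dO[, cols, drop = FALSE]
      da <- dOh %*% t(cc$V[, cols, drop = FALSE])
      dalpha[h, , ] <- da
      dV[, cols] <- dV[, cols] + t(a) %*% dOh
      dS <- a * (da - rowSums(da * a))
      dQ[, cols] <- dQ[, cols] + (dS %*% cc$K[, cols, drop = FALSE]) / sqrt(dk)
      dK[, cols] <- dK[, cols] + (t(dS) %*% cc$Q[, cols, drop = FALSE]) / sqrt(dk)
    }
    dalpha_layers[[l]] <- dalpha
    grads$layers[[l]]$Wq <- grads$layers[[l]]$Wq + t(cc$X) %*% dQ
    grads$layers[[l]]$Wk <- grads$layers[[l]]$Wk + t(cc$X) %*% dK
    grads$layers[[l]]$Wv <- grads$layers[[l]]$Wv + t(cc$X) %*% dV
    dX <- dX + dQ %*% t(par$Wq) + dK %*% t(par$Wk) + dV %*% t(par$Wv)
  }
  # embeddings
  for (t in seq_len(Tt)) {
    grads$E[ids[t], ] <- grads$E[ids[t], ] + dX[t, ]
    grads$P[t, ] <- grads$P[t, ] + dX[t, ]
  }
  list(grads = grads, dalpha = dalpha_layers)
}

# head losses and gradient wrt pooled u for one doc
.tc_head_loss_doc <- function(params, u, targets, weights) {
  du <- u * 0
  loss <- 0
  parts <- list()
  for (task in names(targets)) {
    hd <- params$heads[[task]]
    logit <- as.numeric(u %*% hd$W + hd$b)
    p <- .tc_sigmoid(logit)
    yl <- targets[[task]]
    l_task <- mean(.tc_bce(p, yl))
    parts[[task]] <- l_task
    wgt <- weights[[task]]
    loss <- loss + wgt * l_task
    dlogit <- wgt * (p - yl) / length(yl)
    du <- du + as.numeric(hd$W %*% dlogit)
    attr(parts, paste0("dlogit_", task)) <- dlogit
  }
  list(loss = loss, du = du, parts = parts)
}

#' Train the attention encoder
#'
#' @param texts Character vector of documents.
#' @param labels Primary binary labels (for `tasks = "primary"`), or an
#'   n x 6 / n x 4 binary matrix for emotion / personality auxiliary
#'   models.
#' @param split "train"/"val" per document.
#' @param cfg An `encoder_config`.
#' @param tcfg A `train_config` (use learning_rate 2e-5-ish scaled up for
#'   the from-scratch encoder; default here 1e-3).
#' @param task "primary", "emotion" or "personality".
#' @return A `tc_model` of kind "encoder".
#' @export
train_encoder <- function(texts, labels, split, cfg = encoder_config(),
                          tcfg = train_config(learning_rate = 1e-3),
                          task = "primary") {
  stopifnot(length(texts) == length(split))
  lab_mat <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1L)
  stopifnot(nrow(lab_mat) == length(texts))
  tr <- which(split == "train"); va <- which(split == "val")
  if (!length(tr) || !length(va)) stop("empty train or validation split",
                                       call. = FALSE)
  vocab <- build_vocab(texts[tr], cfg)
  params <- .tc_encoder_init(cfg, length(vocab), tasks = task)
  state <- .tc_adam_init(params)
  enc <- lapply(texts, .tc_encode_ids, vocab = vocab,
                max_tokens = cfg$max_tokens)
  best <- list(acc = -1, params = params)
  history <- list()
  .tc_with_seed(tcfg$seed, 41L, function() {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(tr)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1L, length(ord), by = tcfg$batch_size)) {
        idx <- ord[s:min(s + tcfg$batch_size - 1L, length(ord))]
        grads <- .tc_zero_like(params)
        bl <- 0
        for (b in idx) {
          fwd <- .tc_encoder_forward_doc(params, cfg, enc[[b]]$ids)
          tg <- list(); tg[[task]] <- lab_mat[b, ]
          wt <- list(); wt[[task]] <- 1
          hl <- .tc_head_loss_doc(params, fwd$u, tg, wt)
          bl <- bl + hl$loss
          dl <- attr(hl$parts, paste0("dlogit_", task))
          hd <- params$heads[[task]]
          grads$heads[[task]]$W <- grads$heads[[task]]$W +
            outer(fwd$u, dl)
          grads$heads[[task]]$b <- grads$heads[[task]]$b + dl
          grads <- .tc_encoder_backward_doc(params, cfg, enc[[b]]$ids, fwd,
                                            hl$du, grads)$grads
        }
        grads <- rapply(grads, function(g) g / length(idx), how = "replace")
        stp <- .tc_adam_step(params, grads, state, tcfg$learning_rate,
                             tcfg$weight_decay)
        params <<- stp$params; state <<- stp$state
        ep_loss <- ep_loss + bl / length(idx); nb <- nb + 1L
      }
      pv <- vapply(va, function(b) {
        fwd <- .tc_encoder_forward_doc(params, cfg, enc[[b]]$ids)
        hd <- params$heads[[task]]
        mean((.tc_sigmoid(as.numeric(fwd$u %*% hd$W + hd$b)) >= 0.5) ==
               lab_mat[b, ])
      }, numeric(1))
      acc <- mean(pv)
      history[[ep]] <<- data.frame(epoch = ep, split = "val",
                                   loss = ep_loss / nb, accuracy = acc)
      if (acc > best$acc) best <<- list(acc = acc, params = params)
    }
  })
  structure(list(kind = "encoder", cfg = cfg, tcfg = tcfg, task = task,
                 vocab = vocab, params = best$params,
                 val_accuracy = best$acc,
                 history = do.call(rbind, history)),
            class = "tc_model")
}

.tc_encoder_predict <- function(model, texts, task = NULL) {
  task <- task %||% model$task %||% "primary"
  if (task == "primary" && is.null(model$params$heads$primary)) {
    task <- model$task
  }
  if (is.null(model$params$heads[[task]])) {
    stop("model has no '", task, "' head", call. = FALSE)
  }
  hd <- model$params$heads[[task]]
  out <- t(vapply(texts, function(tx) {
    en <- .tc_encode_ids(tx, model$vocab, model$cfg$max_tokens)
    fwd <- .tc_encoder_forward_doc(model$params, model$cfg, en$ids)
    .tc_sigmoid(as.numeric(fwd$u %*% hd$W + hd$b))
  }, numeric(ncol(hd$W))))
  if (ncol(hd$W) == 1L) as.numeric(out) else out
}
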