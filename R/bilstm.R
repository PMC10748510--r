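# Contour sequence classifier: a stacked bidirectional LSTM over the
# per-window feature vectors, followed by a 2-layer ReLU feed-forward head
# and a sigmoid output. The classifier head consumes the concatenation of
# the last forward and last backward hidden state of the top layer.
# Forward and backward passes are hand-written so training is fully
# self-contained and deterministic under the configured seed.

#' BiLSTM configuration
#'
#' @param n_layers Number of stacked bidirectional layers (default 3).
#' @param hidden_dim Hidden state dimension per direction (default 512).
#' @param head_dim Width of the two ReLU feed-forward head layers
#'   (default 64).
#' @param input_width Feature-vector width per window.
#' @param seed Initialisation/shuffling seed.
#' @return A `bilstm_config`.
#' @export
bilstm_config <- function(n_layers = 3L, hidden_dim = 512L, head_dim = 64L,
                          input_width, seed = 1L) {
  stopifnot(n_layers >= 1L, hidden_dim >= 1L, input_width >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 head_dim = as.integer(head_dim),
                 input_width = as.integer(input_width),
                 seed = as.integer(seed)),
            class = "bilstm_config")
}

#' Training configuration
#'
#' Defaults follow the training contract used throughout: batch size 32,
#' 8 epochs, model selection by best validation accuracy; learning rate
#' 1e-3 for the BiLSTM and 2e-5 for the attention encoder; weight decay
#' 1e-5.
#'
#' @param learning_rate,weight_decay,batch_size,epochs Optimiser settings.
#' @param seed Seed for batch shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-5,
                         batch_size = 32L, epochs = 8L, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1L,
            epochs >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

.tc_bilstm_init <- function(cfg) {
  .tc_with_seed(cfg$seed, 11L, function() {
    H <- cfg$hidden_dim
    mk_dir <- function(d_in) {
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1  # forget-gate bias
      list(W = .tc_glorot(d_in, 4 * H), U = .tc_glorot(H, 4 * H), b = b)
    }
    layers <- list()
    for (l in seq_len(cfg$n_layers)) {
      d_in <- if (l == 1L) cfg$input_width else 2L * H
      layers[[l]] <- list(fw = mk_dir(d_in), bw = mk_dir(d_in))
    }
    hd <- cfg$head_dim
    head <- list(W1 = .tc_glorot(2 * H, hd), b1 = numeric(hd),
                 W2 = .tc_glorot(hd, hd), b2 = numeric(hd),
                 W3 = .tc_glorot(hd, 1L), b3 = numeric(1))
    list(layers = layers, head = head)
  })
}

#' Closed-form parameter count of a stacked BiLSTM
#'
#' Per layer and direction: 4 (d_in H + H^2 + H) with d_in the feature
#' width at layer 1 and 2H above; plus the feed-forward head.
#'
#' @param cfg A `bilstm_config`.
#' @param include_head Count the classifier head too (default TRUE).
#' @return Integer parameter count.
#' @export
bilstm_param_count <- function(cfg, include_head = TRUE) {
  H <- cfg$hidden_dim
  total <- 0
  for (l in seq_len(cfg$n_layers)) {
    d_in <- if (l == 1L) cfg$input_width else 2L * H
    total <- total + 2 * 4 * (d_in * H + H * H + H)
  }
  if (include_head) {
    hd <- cfg$head_dim
    total <- total + (2 * H * hd + hd) + (hd * hd + hd) + (hd + 1)
  }
  total
}

# pad a list of W_i x D matrices into (B, T, D) with mask (B, T)
.tc_pad_batch <- function(xs) {
  B <- length(xs)
  Tmax <- max(vapply(xs, nrow, integer(1)))
  D <- ncol(xs[[1]])
  A <- array(0, dim = c(B, Tmax, D))
  M <- matrix(0, B, Tmax)
  for (b in seq_len(B)) {
    w <- nrow(xs[[b]])
    A[b, seq_len(w), ] <- xs[[b]]
    M[b, seq_len(w)] <- 1
  }
  list(A = A, M = M)
}

# one-direction LSTM forward over (B,T,D); returns outputs (B,T,H) + cache
.tc_lstm_forward_dir <- function(A, M, par, H) {
  B <- dim(A)[1]; Tt <- dim(A)[2]
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  Hout <- array(0, dim = c(B, Tt, H))
  cache <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    x_t <- matrix(A[, t, ], nrow = B)
    a <- x_t %*% par$W + h %*% par$U +
      matrix(par$b, B, 4 * H, byrow = TRUE)
    i <- .tc_sigmoid(a[, 1:H, drop = FALSE])
    f <- .tc_sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .tc_sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cst + i * g
    tc_ <- tanh(c_new)
    h_new <- o * tc_
    m <- M[, t]
    cache[[t]] <- list(x = x_t, i = i, f = f, g = g, o = o,
                       c_prev = cst, h_prev = h, c_new = c_new, tanh_c = tc_)
    cst <- m * c_new + (1 - m) * cst
    h <- m * h_new + (1 - m) * h
    Hout[, t, ] <- h
  }
  list(H = Hout, cache = cache, h_final = h)
}

# matching backward; dHout (B,T,H) holds grads wrt post-mask h at each t
.tc_lstm_backward_dir <- function(dHout, M, par, cache, H) {
  B <- dim(dHout)[1]; Tt <- dim(dHout)[2]
  D <- nrow(par$W)
  dW <- par$W * 0; dU <- par$U * 0; db <- par$b * 0
  dX <- array(0, dim = c(B, Tt, D))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    cc <- cache[[t]]
    m <- M[, t]
    dht <- matrix(dHout[, t, ], nrow = B) + dh
    dh_new <- m * dht
    dh_skip <- (1 - m) * dht
    dc_new <- m * dc
    dc_skip <- (1 - m) * dc
    do_ <- dh_new * cc$tanh_c
    dc_new <- dc_new + dh_new * cc$o * (1 - cc$tanh_c^2)
    di <- dc_new * cc$g
    df <- dc_new * cc$c_prev
    dg <- dc_new * cc$i
    dc_prev <- dc_new * cc$f + dc_skip
    dai <- di * cc$i * (1 - cc$i)
    daf <- df * cc$f * (1 - cc$f)
    dag <- dg * (1 - cc$g^2)
    dao <- do_ * cc$o * (1 - cc$o)
    da <- cbind(dai, daf, dag, dao)
    dW <- dW + t(cc$x) %*% da
    dU <- dU + t(cc$h_prev) %*% da
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(par$W)
    dh <- da %*% t(par$U) + dh_skip
    dc <- dc_prev
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

.tc_rev_time <- function(A) {
  Tt <- dim(A)[2]
  if (length(dim(A)) == 3L) A[, rev(seq_len(Tt)), , drop = FALSE]
  else A[, rev(seq_len(Tt)), drop = FALSE]
}

# full stacked-BiLSTM forward; returns final concat state + caches
.tc_bilstm_forward <- function(params, A, M, H) {
  caches <- list()
  X <- A
  for (l in seq_along(params$layers)) {
    par <- params$layers[[l]]
    fw <- .tc_lstm_forward_dir(X, M, par$fw, H)
    Ar <- .tc_rev_time(X); Mr <- .tc_rev_time(M)
    bwr <- .tc_lstm_forward_dir(Ar, Mr, par$bw, H)
    Hbw <- .tc_rev_time(bwr$H)
    caches[[l]] <- list(fw = fw, bw = bwr, X = X)
    B <- dim(X)[1]; Tt <- dim(X)[2]
    Xn <- array(0, dim = c(B, Tt, 2L * H))
    Xn[, , seq_len(H)] <- fw$H
    Xn[, , H + seq_len(H)] <- Hbw
    X <- Xn
  }
  z <- cbind(caches[[length(caches)]]$fw$h_final,
             caches[[length(caches)]]$bw$h_final)
  list(z = z, caches = caches)
}

.tc_head_forward <- function(head, z) {
  a1 <- z %*% head$W1 + matrix(head$b1, nrow(z), length(head$b1), byrow = TRUE)
  r1 <- pmax(a1, 0)
  a2 <- r1 %*% head$W2 + matrix(head$b2, nrow(z), length(head$b2), byrow = TRUE)
  r2 <- pmax(a2, 0)
  logit <- r2 %*% head$W3 + head$b3
  list(p = .tc_sigmoid(logit), r1 = r1, r2 = r2, a1 = a1, a2 = a2)
}

# full forward + backward for one batch; returns loss, probs and grads
.tc_bilstm_grads <- function(params, A, M, y, H) {
  fwd <- .tc_bilstm_forward(params, A, M, H)
  hf <- .tc_head_forward(params$head, fwd$z)
  B <- length(y)
  loss <- mean(.tc_bce(hf$p, y))
  dlogit <- matrix((hf$p - y) / B, ncol = 1)
  g_head <- list(
    W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
    W3 = t(hf$r2) %*% dlogit, b3 = sum(dlogit))
  dr2 <- dlogit %*% t(params$head$W3)
  da2 <- dr2 * (hf$a2 > 0)
  g_head$W2 <- t(hf$r1) %*% da2
  g_head$b2 <- colSums(da2)
  dr1 <- da2 %*% t(params$head$W2)
  da1 <- dr1 * (hf$a1 > 0)
  g_head$W1 <- t(fwd$z) %*% da1
  g_head$b1 <- colSums(da1)
  dz <- da1 %*% t(params$head$W1)

  L <- length(params$layers)
  g_layers <- vector("list", L)
  Bn <- dim(A)[1]
  dX_next <- NULL  # grad wrt concat output of layer l (B,T,2H)
  for (l in rev(seq_len(L))) {
    cc <- fwd$caches[[l]]
    Tt <- dim(cc$X)[2]
    dH_fw <- array(0, dim = c(Bn, Tt, H))
    dH_bw_rev <- array(0, dim = c(Bn, Tt, H))
    if (l == L) {
      dH_fw[, Tt, ] <- dz[, seq_len(H)]
      # backward-direction final state lives at reversed-time Tt
      dH_bw_rev[, Tt, ] <- dz[, H + seq_len(H)]
    }
    if (!is.null(dX_next)) {
      dH_fw <- dH_fw + dX_next[, , seq_len(H), drop = FALSE]
      dH_bw_rev <- dH_bw_rev +
        .tc_rev_time(dX_next[, , H + seq_len(H), drop = FALSE])
    }
    Mr <- .tc_rev_time(M)
    bk_fw <- .tc_lstm_backward_dir(dH_fw, M, params$layers[[l]]$fw,
                                   cc$fw$cache, H)
    bk_bw <- .tc_lstm_backward_dir(dH_bw_rev, Mr, params$layers[[l]]$bw,
                                   cc$bw$cache, H)
    g_layers[[l]] <- list(
      fw = list(W = bk_fw$dW, U = bk_fw$dU, b = bk_fw$db),
      bw = list(W = bk_bw$dW, U = bk_bw$dU, b = bk_bw$db))
    dX_next <- bk_fw$dX + .tc_rev_time(bk_bw$dX)
    if (l > 1L) {
      # dX_next is grad wrt layer (l-1) concat output, dims already 2H
    }
  }
  list(loss = loss, p = as.numeric(hf$p),
       grads = list(layers = g_layers, head = g_head))
}

#' Train a BiLSTM contour classifier
#'
#' @param x List of W_i x D standardized contour matrices (training +
#'   validation documents).
#' @param y Binary labels aligned with `x`.
#' @param split Character vector ("train"/"val") aligned with `x`.
#' @param cfg A `bilstm_config` (its `input_width` must match D).
#' @param tcfg A `train_config`.
#' @param verbose Print per-epoch metrics.
#' @return A `tc_model` of kind "bilstm" exposing `predict_proba` via
#'   [predict_proba()], with the epoch metrics log in `$history` and the
#'   best-validation-accuracy checkpoint in `$params`.
#' @export
train_bilstm <- function(x, y, split, cfg, tcfg = train_config(),
                         verbose = FALSE) {
  stopifnot(length(x) == length(y), length(y) == length(split))
  widths <- vapply(x, ncol, integer(1))
  if (any(widths != cfg$input_width)) {
    stop("contour width mismatch: expected ", cfg$input_width,
         ", found ", paste(unique(widths), collapse = "/"), call. = FALSE)
  }
  w0 <- vapply(x, nrow, integer(1)) == 0L
  if (any(w0)) {
    warning(sum(w0), " document(s) with zero windows excluded", call. = FALSE)
    x <- x[!w0]; y <- y[!w0]; split <- split[!w0]
  }
  tr <- which(split == "train"); va <- which(split == "val")
  if (!length(tr) || !length(va)) {
    stop("empty train or validation split", call. = FALSE)
  }
  params <- .tc_bilstm_init(cfg)
  state <- .tc_adam_init(params)
  H <- cfg$hidden_dim
  best <- list(acc = -1, params = params)
  history <- list()
  .tc_with_seed(tcfg$seed, 21L, function() {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(tr)
      ep_loss <- 0; nb <- 0L
      for (s in seq(1L, length(ord), by = tcfg$batch_size)) {
        idx <- ord[s:min(s + tcfg$batch_size - 1L, length(ord))]
        pb <- .tc_pad_batch(x[idx])
        gr <- .tc_bilstm_grads(params, pb$A, pb$M, y[idx], H)
        stp <- .tc_adam_step(params, gr$grads, state, tcfg$learning_rate,
                             tcfg$weight_decay)
        params <<- stp$params; state <<- stp$state
        ep_loss <- ep_loss + gr$loss; nb <- nb + 1L
      }
      pv <- .tc_bilstm_predict(params, x[va], H)
      acc <- mean((pv >= 0.5) == y[va])
      history[[ep]] <<- data.frame(epoch = ep, split = "val",
                                   loss = ep_loss / nb, accuracy = acc)
      if (acc > best$acc) best <<- list(acc = acc, params = params)
      if (verbose) {
        message(sprintf("epoch %d: train loss %.4f, val acc %.4f",
                        ep, ep_loss / nb, acc))
      }
    }
  })
  structure(list(kind = "bilstm", cfg = cfg, tcfg = tcfg,
                 params = best$params, val_accuracy = best$acc,
                 history = do.call(rbind, history)),
            class = "tc_model")
}

.tc_bilstm_predict <- function(params, xs, H, batch_size = 64L) {
  out <- numeric(length(xs))
  for (s in seq(1L, length(xs), by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, length(xs))
    pb <- .tc_pad_batch(xs[idx])
    fwd <- .tc_bilstm_forward(params, pb$A, pb$M, H)
    out[idx] <- as.numeric(.tc_head_forward(params$head, fwd$z)$p)
  }
  out
}

#' Predict class probabilities
#'
#' @param model A `tc_model`.
#' @param newdata For "bilstm" models, a list of contour matrices; for
#'   encoder models, a character vector of texts.
#' @param ... Passed to methods.
#' @return Numeric probabilities (or a matrix for multi-output heads).
#' @export
predict_proba <- function(model, newdata, ...) UseMethod("predict_proba")

#' @export
predict_proba.tc_model <- function(model, newdata, task = "primary", ...) {
  if (model$kind == "bilstm") {
    return(.tc_bilstm_predict(model$params, newdata, model$cfg$hidden_dim))
  }
  .tc_encoder_predict(model, newdata, task = task)
}

#' @export
predict_proba.function <- function(model, newdata, ...) model(newdata)

#' @export
print.tc_model <- function(x, ...) {
  cat("<tc_model> kind=", x$kind,
      if (!is.null(x$val_accuracy)) paste0(" val_acc=",
                                           round(x$val_accuracy, 4)),
      "\n", sep = "")
  invisible(x)
}

#' Save a trained model checkpoint
#'
#' Opaque, versioned checkpoint (RDS payload behind a version header);
#' [load_checkpoint()] refuses incompatible versions.
#'
#' @param model A `tc_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tc_model"))
  saveRDS(list(format = "textcontours-checkpoint", version = 1L,
               model = model), path)
  invisible(path)
}

#' Load a trained model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return The `tc_model`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "textcontours-checkpoint") ||
      !identical(x$version, 1L)) {
    stop("not a compatible checkpoint file: ", path, call. = FALSE)
  }
  x$model
}
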