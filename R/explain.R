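# Layered explanation suite.
#
# - LIME: perturbs a document in bag-of-unigrams space, queries the model
#   on each perturbation, and fits a proximity-weighted ridge surrogate.
# - SP-LIME: greedy submodular pick of representative instances whose
#   local surrogate weights are aggregated into normalized per-group
#   importance (contour models).
# - AGRAD: importance of an attention position as minus the gradient of
#   the loss with respect to its post-softmax weight times the weight.

.tc_ridge <- function(Z, y, w, alpha = 1) {
  X <- cbind(1, Z)
  WX <- X * w
  A <- t(X) %*% WX
  diag(A)[-1] <- diag(A)[-1] + alpha
  beta <- solve(A, t(WX) %*% y)
  as.numeric(beta[-1])
}

#' LIME explanation of one document
#'
#' Samples binary masks over the document's distinct unigrams, removes the
#' masked-out words, queries the model, and fits a ridge surrogate with an
#' exponential proximity kernel (width 25 on the 0-100 cosine-distance
#' scale, the reference defaults). One attribution per distinct unigram.
#'
#' @param model A `tc_model` (encoder/fusion) or a function
#'   `texts -> probabilities`.
#' @param doc A non-empty document string.
#' @param n_samples Number of perturbations (>= 10; default 1000).
#' @param seed RNG seed.
#' @param doc_id Id recorded in the output.
#' @param kernel_width Proximity kernel width (default 25).
#' @return data.frame (doc_id, position, token, importance, method) sorted
#'   by decreasing importance.
#' @export
lime_explain <- function(model, doc, n_samples = 1000L, seed = 1L,
                         doc_id = "doc", kernel_width = 25) {
  if (n_samples < 10L) stop("n_samples must be >= 10", call. = FALSE)
  toks <- tolower(tokenize_words(doc))
  toks <- toks[grepl("[[:alnum:]]", toks)]
  if (!length(toks)) stop("document has no word tokens", call. = FALSE)
  uni <- unique(toks)
  first_pos <- match(uni, toks)
  p <- length(uni)
  .tc_with_seed(seed, 61L, function() {
    Z <- matrix(stats::rbinom(n_samples * p, 1L, 0.5), n_samples, p)
    Z[1L, ] <- 1L  # the instance itself
    texts <- vapply(seq_len(n_samples), function(s) {
      keep <- uni[Z[s, ] == 1L]
      paste(toks[toks %in% keep], collapse = " ")
    }, character(1))
    texts[!nzchar(texts)] <- " "
    y <- as.numeric(predict_proba(model, texts))
    ones <- rep(1, p)
    cosd <- apply(Z, 1L, function(z) {
      nz <- sqrt(sum(z))
      if (nz == 0) 1 else 1 - sum(z) / (nz * sqrt(p))
    })
    w <- exp(-(100 * cosd)^2 / kernel_width^2)
    beta <- .tc_ridge(Z, y, w)
    out <- data.frame(doc_id = doc_id, position = first_pos, token = uni,
                      importance = beta, method = "LIME",
                      stringsAsFactors = FALSE)
    out[order(-out$importance, out$position), ]
  })
}

# local surrogate in contour-feature space: masks feature columns to zero
# (the standardized training mean) and fits the same weighted ridge.
.tc_lime_features <- function(model, xmat, n_samples, seed,
                              kernel_width = 25) {
  D <- ncol(xmat)
  .tc_with_seed(seed, 62L, function() {
    Z <- matrix(stats::rbinom(n_samples * D, 1L, 0.5), n_samples, D)
    Z[1L, ] <- 1L
    xs <- lapply(seq_len(n_samples), function(s) {
      xm <- xmat
      off <- which(Z[s, ] == 0L)
      if (length(off)) xm[, off] <- 0
      xm
    })
    y <- predict_proba(model, xs)
    cosd <- apply(Z, 1L, function(z) {
      nz <- sqrt(sum(z))
      if (nz == 0) 1 else 1 - sum(z) / (nz * sqrt(D))
    })
    w <- exp(-(100 * cosd)^2 / kernel_width^2)
    .tc_ridge(Z, y, w)
  })
}

#' SP-LIME group importance for a contour model
#'
#' Fits a local surrogate per candidate instance, greedily picks a
#' representative instance subset by submodular feature-coverage gain, and
#' aggregates the picked instances' absolute surrogate weights per feature
#' group, normalized so the groups sum to 100.
#'
#' @param model A contour `tc_model` (kind "bilstm") or a function over
#'   lists of contour matrices.
#' @param xs List of standardized contour matrices (the evaluation subset).
#' @param grouping Named list group -> integer feature indices; must
#'   partition `1:ncol`.
#' @param budget Number of instances to pick (default min(50, length(xs))).
#' @param n_samples Perturbations per instance (default 200).
#' @param seed RNG seed.
#' @param top_features Per-instance "explained" feature set size used by
#'   the coverage objective (default 20).
#' @return data.frame (group, importance, rank) with importance in percent
#'   summing to 100.
#' @export
sp_lime_group_importance <- function(model, xs, grouping,
                                     budget = min(50L, length(xs)),
                                     n_samples = 200L, seed = 1L,
                                     top_features = 20L) {
  D <- ncol(xs[[1]])
  idx_all <- sort(unname(unlist(grouping)))
  if (length(idx_all) != D || !identical(idx_all, seq_len(D))) {
    stop("grouping must partition the feature indices 1..", D, call. = FALSE)
  }
  n <- length(xs)
  Wmat <- matrix(0, n, D)
  for (i in seq_len(n)) {
    Wmat[i, ] <- abs(.tc_lime_features(model, xs[[i]], n_samples,
                                       seed = seed + i))
  }
  # sparse surrogate: keep each instance's top-K weights (the K-feature
  # selection step of reference LIME); dense ridge noise otherwise
  # accumulates in proportion to group size
  explained <- lapply(seq_len(n), function(i) {
    utils::head(order(-Wmat[i, ]), top_features)
  })
  for (i in seq_len(n)) {
    keep <- explained[[i]]
    drop <- setdiff(seq_len(D), keep)
    Wmat[i, drop] <- 0
  }
  # greedy submodular pick: coverage of globally important features
  I <- sqrt(colSums(Wmat))
  picked <- integer(0)
  covered <- logical(D)
  for (k in seq_len(min(budget, n))) {
    gains <- vapply(seq_len(n), function(i) {
      if (i %in% picked) return(-Inf)
      sum(I[explained[[i]][!covered[explained[[i]]]]])
    }, numeric(1))
    best <- which.max(gains)
    picked <- c(picked, best)
    covered[explained[[best]]] <- TRUE
  }
  raw <- vapply(grouping, function(ii) sum(Wmat[picked, ii, drop = FALSE]),
                numeric(1))
  total <- sum(raw)
  pct <- if (total == 0) rep(100 / length(raw), length(raw)) else
    100 * raw / total
  out <- data.frame(group = names(grouping), importance = pct,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$importance, ties.method = "first")
  rownames(out) <- NULL
  out
}

#' AGRAD attention-gradient attribution
#'
#' For an attention model, computes per-position importance
#' `A_i = -(dL/d alpha_i) * alpha_i` over the post-softmax attention
#' weights of the final encoder layer, summed over heads and query
#' positions (word-level vocabulary, so sub-token aggregation is the
#' identity). Positive importance means the position reduces the loss for
#' the target label (supports the prediction).
#'
#' @param model An encoder/fusion `tc_model`.
#' @param doc Document string.
#' @param target Target label (default 1).
#' @param doc_id Id recorded in the output.
#' @param layer Encoder layer to attribute (default: final layer).
#' @return data.frame (doc_id, position, token, importance, method).
#' @export
agrad_attribution <- function(model, doc, target = 1L, doc_id = "doc",
                              layer = NULL) {
  if (!inherits(model, "tc_model") || !(model$kind %in% c("encoder", "fusion"))) {
    stop("AGRAD requires a model exposing attention weights ",
         "(encoder or fusion kind)", call. = FALSE)
  }
  ag <- .tc_agrad_raw(model, doc, target, layer)
  imp <- apply(-ag$dalpha * ag$alpha, 3L, sum)  # sum over heads and queries
  data.frame(doc_id = doc_id, position = seq_along(ag$tokens),
             token = ag$tokens, importance = imp, method = "AGRAD",
             stringsAsFactors = FALSE)
}

# raw AGRAD internals: alpha and dL/dalpha at the chosen layer, plus the
# ingredients the finite-difference oracle needs.
.tc_agrad_raw <- function(model, doc, target = 1L, layer = NULL) {
  cfg <- model$cfg
  layer <- layer %||% cfg$n_layers
  en <- .tc_encode_ids(doc, model$vocab, cfg$max_tokens)
  task <- if (model$kind == "fusion" || model$task == "primary")
    "primary" else model$task
  fwd <- .tc_encoder_forward_doc(model$params, cfg, en$ids)
  hd <- model$params$heads[[task]]
  logit <- as.numeric(fwd$u %*% hd$W + hd$b)
  p <- .tc_sigmoid(logit)
  y <- rep_len(target, length(p))
  loss <- mean(.tc_bce(p, y))
  dlogit <- (p - y) / length(y)
  du <- as.numeric(hd$W %*% dlogit)
  grads <- .tc_zero_like(model$params)
  bk <- .tc_encoder_backward_doc(model$params, cfg, en$ids, fwd, du, grads)
  list(tokens = en$tokens, ids = en$ids, loss = loss,
       alpha = fwd$caches[[layer]]$alpha, dalpha = bk$dalpha[[layer]],
       layer = layer, task = task)
}

# loss recomputed with an alpha override at one layer (finite-difference
# oracle support)
.tc_loss_with_alpha <- function(model, doc, target, layer, alpha) {
  cfg <- model$cfg
  en <- .tc_encode_ids(doc, model$vocab, cfg$max_tokens)
  task <- if (model$kind == "fusion" || model$task == "primary")
    "primary" else model$task
  fwd <- .tc_encoder_forward_doc(model$params, cfg, en$ids,
                                 alpha_override = list(layer = layer,
                                                       alpha = alpha))
  hd <- model$params$heads[[task]]
  p <- .tc_sigmoid(as.numeric(fwd$u %*% hd$W + hd$b))
  mean(.tc_bce(p, rep_len(target, length(p))))
}

#' Top-k unigrams per document
#'
#' @param records Attribution data.frame (any method), one or more
#'   documents.
#' @param k Per-document selection size (default 10).
#' @return data.frame of the per-document top-k records, importance
#'   non-increasing within document, ties broken by earlier position;
#'   documents with fewer than k unigrams contribute all of them.
#' @export
top_k_unigrams <- function(records, k = 10L) {
  stopifnot(k >= 1L)
  out <- lapply(split(records, records$doc_id), function(df) {
    df <- df[order(-df$importance, df$position), , drop = FALSE]
    utils::head(df, k)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lexicon-category coverage of selected unigrams
#'
#' Percentage of the selected word tokens that belong to each category
#' (multi-category words count once per category; bigram lexicon entries
#' are ignored since selection is at the unigram level).
#'
#' @param topk data.frame from [top_k_unigrams()].
#' @param lexicon A `tc_lexicon`.
#' @param categories Category names to report.
#' @param model_label Label recorded in the output.
#' @return data.frame (model, category, percentage).
#' @export
category_coverage <- function(topk, lexicon, categories,
                              model_label = "model") {
  missing_cat <- setdiff(categories, names(lexicon$categorical))
  if (length(missing_cat)) {
    stop("categories not in lexicon: ", paste(missing_cat, collapse = ", "),
         call. = FALSE)
  }
  words <- tolower(topk$token)
  n <- length(words)
  if (n == 0L) {
    warning("empty selection; coverage reported as 0", call. = FALSE)
    return(data.frame(model = model_label, category = categories,
                      percentage = 0, stringsAsFactors = FALSE))
  }
  pct <- vapply(categories, function(cat_) {
    wl <- lexicon$categorical[[cat_]]
    wl <- wl[!grepl(" ", wl)]  # unigram entries only
    100 * sum(words %in% wl) / n
  }, numeric(1))
  data.frame(model = model_label, category = categories, percentage = pct,
             stringsAsFactors = FALSE)
}

#' Pearson correlations between gold condition labels and silver labels
#'
#' @param gold Binary vector.
#' @param silver Binary matrix (columns = auxiliary labels) or vector.
#' @param labels Optional column names for the output.
#' @return data.frame (label, r, constant) where `constant` flags pairs
#'   where either vector is constant (r reported as 0, matching the 0.00
#'   table convention).
#' @export
label_correlations <- function(gold, silver, labels = NULL) {
  if (!is.matrix(silver)) silver <- matrix(silver, ncol = 1L)
  if (length(gold) != nrow(silver)) {
    stop("gold and silver label lengths differ", call. = FALSE)
  }
  labels <- labels %||% colnames(silver) %||%
    paste0("aux", seq_len(ncol(silver)))
  res <- lapply(seq_len(ncol(silver)), function(j) {
    s <- silver[, j]
    if (stats::sd(gold) == 0 || stats::sd(s) == 0) {
      data.frame(label = labels[j], r = 0, constant = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = labels[j], r = stats::cor(gold, s),
                 constant = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
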