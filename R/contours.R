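# Sliding-window contour extraction. A window of `w` consecutive sentences
# slides with stride 1 across a document; each GLF is scored once per
# window (dense W x N matrix), each LBF once per window with only non-zero
# scores kept (sparse 3-tuple set). Window ids in the sparse set are
# 0-based, matching the tuple contract (0 <= i < W).

#' Extract text contours from an annotated document
#'
#' @param doc An `annotated_text`.
#' @param registry A `feature_registry` (default [default_registry()]).
#' @param lexicons Named list slot -> `tc_lexicon` covering all LBF slots.
#' @param window_len Window length in sentences (w >= 1; default 1, i.e.
#'   per-sentence scores as in the contour figures).
#' @param resources List with `register_tables` and `easy_words`; default
#'   [default_resources()].
#' @return List with `dense` (a `contour_matrix`) and `sparse`
#'   (a `sparse_contour`).
#' @export
extract_contours <- function(doc, registry = default_registry(), lexicons,
                             window_len = 1L, resources = default_resources(),
                             lbf_ctx = NULL) {
  stopifnot(inherits(doc, "annotated_text"), window_len >= 1L)
  missing_slots <- setdiff(unique(registry$lbf$group), names(lexicons))
  if (length(missing_slots)) {
    stop("no lexicon loaded for slot(s): ",
         paste(missing_slots, collapse = ", "), call. = FALSE)
  }
  T_ <- doc$n_sentences
  W <- max(T_ - window_len + 1L, 0L)
  if (is.null(lbf_ctx)) lbf_ctx <- .tc_build_lbf_ctx(registry, lexicons)
  N <- nrow(registry$glf)
  values <- matrix(0, nrow = W, ncol = N,
                   dimnames = list(NULL, registry$glf$name))
  sparse_rows <- vector("list", W)
  for (i in seq_len(W)) {
    idx <- i:(i + window_len - 1L)
    sents <- doc$sentences[idx]
    prev1 <- if (i > 1L) doc$sentences[[i - 1L]] else NULL
    prev2 <- if (i > 2L) doc$sentences[[i - 2L]] else NULL
    prev_all <- if (i > 1L) do.call(rbind, doc$sentences[seq_len(i - 1L)]) else NULL
    st <- build_window_stats(sents, prev1, prev2, prev_all, resources)
    values[i, ] <- vapply(registry$glf_scorers, function(f) f(st), numeric(1))
    lb <- .tc_score_lbf_window(st, lbf_ctx)
    nz <- which(lb != 0)
    if (length(nz)) {
      sparse_rows[[i]] <- data.frame(feature_id = nz, window_id = i - 1L,
                                     score = lb[nz])
    }
  }
  if (any(!is.finite(values))) {
    stop("non-finite GLF score produced for doc ", doc$doc_id, call. = FALSE)
  }
  entries <- if (any(!vapply(sparse_rows, is.null, logical(1)))) {
    do.call(rbind, sparse_rows)
  } else {
    data.frame(feature_id = integer(0), window_id = integer(0),
               score = numeric(0))
  }
  rownames(entries) <- NULL
  list(
    dense = structure(list(doc_id = doc$doc_id, windows = W, values = values),
                      class = "contour_matrix"),
    sparse = structure(list(doc_id = doc$doc_id, windows = W,
                            n_features = nrow(registry$lbf), entries = entries),
                       class = "sparse_contour")
  )
}

# Precompute fast lookup structures for LBF scoring: a hash map from word
# (or bigram) to the categorical feature ids it belongs to, plus the norm
# value tables keyed by feature id.
.tc_build_lbf_ctx <- function(registry, lexicons) {
  K <- nrow(registry$lbf)
  cat_env <- new.env(hash = TRUE, parent = emptyenv())
  norm_feats <- list()
  for (k in seq_len(K)) {
    slot <- registry$lbf$group[k]
    key <- registry$lbf$key[k]
    lex <- lexicons[[slot]]
    if (registry$lbf$type[k] == "category") {
      for (w in lex$categorical[[key]]) {
        cat_env[[w]] <- c(get0(w, envir = cat_env, ifnotfound = integer(0)), k)
      }
    } else if (!is.null(lex$norms[[key]])) {
      norm_feats[[as.character(k)]] <- lex$norms[[key]]
    }
  }
  list(K = K, cat_env = cat_env, norm_feats = norm_feats)
}

# Score all LBFs for one window; returns numeric vector of length K in
# registry order. Categorical lexicons: (unigram + bigram hits) / window
# token count, where a token matches on its lowercase surface or,
# failing that, its lemma. Norm lexicons: mean norm value over matched
# words, 0 when nothing matches.
.tc_score_lbf_window <- function(st, ctx) {
  out <- numeric(ctx$K)
  if (st$n_tok == 0L) return(out)
  surf <- st$surfaces
  lem <- tolower(st$lemmas)
  counts <- numeric(ctx$K)
  for (j in seq_along(surf)) {
    ids <- get0(surf[j], envir = ctx$cat_env, ifnotfound = NULL)
    if (is.null(ids)) ids <- get0(lem[j], envir = ctx$cat_env,
                                  ifnotfound = integer(0))
    else ids <- unique(c(ids, get0(lem[j], envir = ctx$cat_env,
                                   ifnotfound = integer(0))))
    if (length(ids)) counts[ids] <- counts[ids] + 1
  }
  for (b in st$bigrams) {
    ids <- get0(b, envir = ctx$cat_env, ifnotfound = NULL)
    if (!is.null(ids)) counts[ids] <- counts[ids] + 1
  }
  out <- counts / st$n_tok
  for (kch in names(ctx$norm_feats)) {
    v <- ctx$norm_feats[[kch]]
    x <- v[surf]
    miss <- is.na(x)
    if (any(miss)) x[miss] <- v[lem[miss]]
    x <- x[!is.na(x)]
    if (length(x)) out[as.integer(kch)] <- mean(x)
  }
  out
}

#' @export
print.contour_matrix <- function(x, ...) {
  cat("<contour_matrix> ", x$doc_id, ": ", x$windows, " window(s) x ",
      ncol(x$values), " GLFs\n", sep = "")
  invisible(x)
}

#' @export
print.sparse_contour <- function(x, ...) {
  cat("<sparse_contour> ", x$doc_id, ": ", nrow(x$entries),
      " non-zero tuple(s) over ", x$windows, " window(s)\n", sep = "")
  invisible(x)
}

#' Densify a sparse contour
#'
#' @param sp A `sparse_contour`.
#' @return W x K matrix with zeros at unlisted positions.
#' @export
densify_contour <- function(sp) {
  stopifnot(inherits(sp, "sparse_contour"))
  m <- matrix(0, nrow = sp$windows, ncol = sp$n_features)
  if (nrow(sp$entries)) {
    m[cbind(sp$entries$window_id + 1L, sp$entries$feature_id)] <- sp$entries$score
  }
  m
}

#' Sparsify a dense LBF matrix
#'
#' Inverse of [densify_contour()]: emits a tuple iff the score is non-zero.
#'
#' @param m W x K matrix.
#' @param doc_id Document id for the result.
#' @return A `sparse_contour`.
#' @export
sparsify_contour <- function(m, doc_id = "doc") {
  nz <- which(m != 0, arr.ind = TRUE)
  entries <- data.frame(feature_id = as.integer(nz[, 2]),
                        window_id = as.integer(nz[, 1]) - 1L,
                        score = m[nz])
  entries <- entries[order(entries$window_id, entries$feature_id), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(list(doc_id = doc_id, windows = nrow(m), n_features = ncol(m),
                 entries = entries),
            class = "sparse_contour")
}

#' Z-standardize (and optionally b-spline smooth) a contour
#'
#' Z-scores use the population standard deviation; a zero-variance sequence
#' maps to all zeros. Smoothing fits a cubic b-spline regression to the
#' standardized sequence and evaluates it at the original positions
#' (length-preserving); it is intended for plotting only and is off by
#' default.
#'
#' @param contour Numeric vector (length >= 1).
#' @param smooth Logical; apply cubic b-spline smoothing.
#' @param df Spline degrees of freedom (default ~ length/3, at least 4).
#' @return Numeric vector of the same length.
#' @export
standardize_and_smooth <- function(contour, smooth = FALSE, df = NULL) {
  stopifnot(is.numeric(contour), length(contour) >= 1L)
  mu <- mean(contour)
  sdev <- sqrt(mean((contour - mu)^2))
  z <- if (sdev == 0) rep(0, length(contour)) else (contour - mu) / sdev
  if (!smooth || length(z) < 5L) return(z)
  x <- seq_along(z)
  if (is.null(df)) df <- max(4L, min(length(z) - 1L, ceiling(length(z) / 3)))
  basis <- splines::bs(x, df = df, degree = 3L)
  fit <- stats::lm.fit(cbind(1, basis), z)
  as.numeric(cbind(1, basis) %*% fit$coefficients)
}

#' Fit per-feature standardization statistics on a training split
#'
#' Column means and population SDs over all windows of all training
#' documents, for the concatenated GLF + LBF feature space. Applying a
#' scaler fitted on the training split to validation/test avoids leaking
#' evaluation statistics into model input.
#'
#' @param contours List of `list(dense=, sparse=)` pairs from
#'   [extract_contours()].
#' @return A `contour_scaler` (means, sds, widths).
#' @export
fit_contour_scaler <- function(contours) {
  stopifnot(length(contours) >= 1L)
  mats <- lapply(contours, function(cc) {
    cbind(cc$dense$values, densify_contour(cc$sparse))
  })
  big <- do.call(rbind, mats)
  mu <- colMeans(big)
  sds <- sqrt(colMeans(sweep(big, 2L, mu)^2))
  structure(list(mean = mu, sd = sds,
                 n_glf = ncol(contours[[1]]$dense$values),
                 n_lbf = contours[[1]]$sparse$n_features),
            class = "contour_scaler")
}

#' Standardize one document's contours into a model input matrix
#'
#' @param cc A `list(dense=, sparse=)` pair.
#' @param scaler A `contour_scaler` from [fit_contour_scaler()].
#' @param features "all", "glf" or "lbf" — which block(s) to emit.
#' @return W x D standardized matrix (zero-variance columns pinned to 0).
#' @export
apply_contour_scaler <- function(cc, scaler, features = c("all", "glf", "lbf")) {
  features <- match.arg(features)
  full <- cbind(cc$dense$values, densify_contour(cc$sparse))
  sds <- ifelse(scaler$sd == 0, 1, scaler$sd)
  z <- sweep(sweep(full, 2L, scaler$mean), 2L, sds, "/")
  idx <- switch(features,
                all = seq_len(ncol(z)),
                glf = seq_len(scaler$n_glf),
                lbf = scaler$n_glf + seq_len(scaler$n_lbf))
  z[, idx, drop = FALSE]
}

#' Write contour pair to CSV cache files
#'
#' Dense contours as a columnar CSV, sparse contours as a 3-column tuple
#' CSV (`feature_id,window_id,score`).
#'
#' @param cc A `list(dense=, sparse=)` pair.
#' @param dense_path,sparse_path Output paths.
#' @export
write_contours <- function(cc, dense_path, sparse_path) {
  utils::write.csv(as.data.frame(cc$dense$values), dense_path,
                   row.names = FALSE)
  utils::write.csv(cc$sparse$entries, sparse_path, row.names = FALSE)
  invisible(NULL)
}

#' Read a contour pair from CSV cache files
#'
#' @param dense_path,sparse_path Paths written by [write_contours()].
#' @param doc_id Document id.
#' @param n_lbf Width of the sparse feature space.
#' @return A `list(dense=, sparse=)` pair.
#' @export
read_contours <- function(dense_path, sparse_path, doc_id = "doc",
                          n_lbf = 306L) {
  dv <- as.matrix(utils::read.csv(dense_path, check.names = FALSE))
  en <- utils::read.csv(sparse_path)
  list(
    dense = structure(list(doc_id = doc_id, windows = nrow(dv), values = dv),
                      class = "contour_matrix"),
    sparse = structure(list(doc_id = doc_id, windows = nrow(dv),
                            n_features = n_lbf, entries = en),
                       class = "sparse_contour"))
}
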