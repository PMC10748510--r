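# Pipeline glue: corpus -> annotated docs -> contours -> standardized
# model-input dataset.

#' Build a contour dataset from a corpus
#'
#' Annotates every document, extracts dense GLF and sparse LBF contours,
#' fits per-feature standardization statistics on the training split only,
#' and assembles the standardized input matrices for the requested feature
#' block. Documents with zero windows are excluded with a warning.
#'
#' @param corpus A `tc_corpus`.
#' @param registry A `feature_registry`.
#' @param lexicons Named list of `tc_lexicon`s covering all slots.
#' @param features "all" (GLF + LBF concatenated along the feature axis),
#'   "glf" or "lbf".
#' @param window_len Sliding-window length in sentences (default 1).
#' @param resources Extraction resources (see [default_resources()]).
#' @return List with `x` (list of W x D standardized matrices), `y`,
#'   `split`, `ids`, `scaler`, `grouping` (named list of feature-index
#'   groups for the selected block) and `input_width`.
#' @export
build_contour_dataset <- function(corpus, registry = default_registry(),
                                  lexicons, features = "all",
                                  window_len = 1L,
                                  resources = default_resources()) {
  contours <- vector("list", nrow(corpus))
  lbf_ctx <- .tc_build_lbf_ctx(registry, lexicons)
  for (i in seq_len(nrow(corpus))) {
    doc <- annotate(corpus$text[i], doc_id = corpus$id[i])
    contours[[i]] <- extract_contours(doc, registry, lexicons,
                                      window_len = window_len,
                                      resources = resources,
                                      lbf_ctx = lbf_ctx)
  }
  w <- vapply(contours, function(cc) cc$dense$windows, integer(1))
  keep <- w > 0L
  if (any(!keep)) {
    warning(sum(!keep), " document(s) with zero windows excluded",
            call. = FALSE)
  }
  contours <- contours[keep]
  split <- corpus$split[keep]
  tr <- which(split == "train")
  if (!length(tr)) stop("no training documents after filtering", call. = FALSE)
  scaler <- fit_contour_scaler(contours[tr])
  x <- lapply(contours, apply_contour_scaler, scaler = scaler,
              features = features)
  list(x = x, y = corpus$label[keep], split = split, ids = corpus$id[keep],
       scaler = scaler, contours = contours,
       grouping = feature_grouping(registry, features),
       input_width = ncol(x[[1]]))
}

#' Feature-index grouping for SP-LIME aggregation
#'
#' @param registry A `feature_registry`.
#' @param features "all", "glf" or "lbf" — the input block the indices
#'   refer to. For "glf" the groups are the five GLF groups; for "lbf" the
#'   seven lexicon slots; for "all" both (LBF indices offset by the GLF
#'   width).
#' @return Named list of integer index vectors partitioning the block.
#' @export
feature_grouping <- function(registry, features = "all") {
  glf_groups <- split(seq_len(nrow(registry$glf)), registry$glf$group)
  lbf_groups <- split(seq_len(nrow(registry$lbf)), registry$lbf$group)
  switch(features,
         glf = glf_groups,
         lbf = lbf_groups,
         all = c(glf_groups,
                 lapply(lbf_groups, function(ii) ii + nrow(registry$glf))))
}
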