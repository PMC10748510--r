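# Evaluation metrics and report arithmetic: accuracy/precision/recall/F1
# rows, F1 gaps between interpretable and reference models, fusion accuracy
# gains, and total normalized importance scores summed across conditions.

#' Classification metrics row
#'
#' Accuracy, precision, recall and F1 in percent. Averaging is "macro"
#' (default): precision and recall are averaged over the two classes and
#' F1 is their harmonic mean, so the F1 = 2PR/(P+R) identity holds on
#' every row; or "positive" for positive-class metrics. Zero-division
#' cells are reported as 0 and flagged.
#'
#' @param gold,pred Binary vectors of equal non-zero length.
#' @param average "macro" or "positive".
#' @param model,condition Labels recorded in the row.
#' @return data.frame (model, condition, accuracy, f1, precision, recall,
#'   zero_division) with values in [0, 100].
#' @export
classification_metrics <- function(gold, pred, average = c("macro", "positive"),
                                   model = "model", condition = "condition") {
  average <- match.arg(average)
  if (length(gold) != length(pred) || length(gold) == 0L) {
    stop("gold and pred must have equal non-zero length", call. = FALSE)
  }
  gold <- as.integer(gold); pred <- as.integer(pred)
  zero_div <- FALSE
  prf <- function(cls) {
    tp <- sum(pred == cls & gold == cls)
    fp <- sum(pred == cls & gold != cls)
    fn <- sum(pred != cls & gold == cls)
    p <- if (tp + fp == 0) {zero_div <<- TRUE; 0} else tp / (tp + fp)
    r <- if (tp + fn == 0) {zero_div <<- TRUE; 0} else tp / (tp + fn)
    c(p = p, r = r)
  }
  acc <- mean(gold == pred)
  if (average == "macro") {
    m <- (prf(1L) + prf(0L)) / 2
  } else {
    m <- prf(1L)
  }
  p <- m[["p"]]; r <- m[["r"]]
  f1 <- if (p + r == 0) {zero_div <- TRUE; 0} else 2 * p * r / (p + r)
  data.frame(model = model, condition = condition,
             accuracy = 100 * acc, f1 = 100 * f1,
             precision = 100 * p, recall = 100 * r,
             zero_division = zero_div, stringsAsFactors = FALSE)
}

#' F1 gap between the best interpretable model and the reference model
#'
#' @param metrics data.frame with columns model, type ("interpretable" or
#'   "reference"), condition, f1.
#' @param condition Condition to compare.
#' @return Signed delta: max interpretable F1 minus reference F1.
#' @export
f1_gap <- function(metrics, condition) {
  rows <- metrics[metrics$condition == condition, , drop = FALSE]
  intp <- rows$f1[rows$type == "interpretable"]
  ref <- rows$f1[rows$type == "reference"]
  if (!length(intp) || length(ref) != 1L) {
    stop("need >= 1 interpretable row and exactly 1 reference row for '",
         condition, "'", call. = FALSE)
  }
  max(intp) - ref
}

#' Accuracy gain from information infusion
#'
#' @param fusion data.frame with columns model, condition, accuracy (the
#'   fusion-model table).
#' @param baseline data.frame with columns condition, accuracy (the
#'   reference-model rows).
#' @param condition Condition.
#' @param variant Fusion variant (value of `fusion$model`).
#' @return Signed delta: fusion accuracy minus baseline accuracy.
#' @export
infusion_gain <- function(fusion, baseline, condition, variant) {
  fr <- fusion[fusion$condition == condition & fusion$model == variant, ,
               drop = FALSE]
  br <- baseline[baseline$condition == condition, , drop = FALSE]
  if (nrow(fr) != 1L || nrow(br) != 1L) {
    stop("missing fusion or baseline row for '", condition, "' / '",
         variant, "'", call. = FALSE)
  }
  fr$accuracy - br$accuracy
}

#' Total normalized importance score across conditions
#'
#' Arithmetic sum of one importance value per condition, reported to two
#' decimals.
#'
#' @param values Numeric vector with exactly one value per condition
#'   (length 5 for the five-condition report).
#' @param n_conditions Expected length (default 5).
#' @return Sum, rounded half-up to 2 decimals.
#' @export
total_importance <- function(values, n_conditions = 5L) {
  if (length(values) != n_conditions || anyNA(values)) {
    stop("expected exactly ", n_conditions, " condition values",
         call. = FALSE)
  }
  floor(sum(values) * 100 + 0.5) / 100
}

#' Read a bundled printed reference table
#'
#' The published benchmark tables shipped as TSV under `extdata/` (model
#' performance, feature-group importance, fusion performance, external
#' benchmarks). These are report inputs for the aggregation arithmetic;
#' the package does not recompute their cells.
#'
#' @param name One of "performance", "glf_importance", "lbf_importance",
#'   "fusion", "benchmarks".
#' @return data.frame.
#' @export
reference_table <- function(name = c("performance", "glf_importance",
                                     "lbf_importance", "fusion",
                                     "benchmarks")) {
  name <- match.arg(name)
  fname <- c(performance = "table_performance.tsv",
             glf_importance = "table_glf_importance.tsv",
             lbf_importance = "table_lbf_importance.tsv",
             fusion = "table_fusion.tsv",
             benchmarks = "table_benchmarks.tsv")[[name]]
  path <- system.file("extdata", fname, package = "textcontours")
  if (!nzchar(path)) stop("bundled table not found: ", fname, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Render a metrics table as Markdown
#'
#' @param df data.frame.
#' @param digits Decimal places for numeric columns (default 2).
#' @return Character vector of Markdown lines.
#' @export
render_markdown_table <- function(df, digits = 2L) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, format = "f", digits = digits)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1L, function(rr) paste0("| ", paste(rr, collapse = " | "), " |"))
  c(header, sep, rows)
}
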