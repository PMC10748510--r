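# Line-delimited JSON corpus I/O. One record per line with fields:
# id, text, label (0/1), optional split ("train"/"val"/"test"), optional
# emotion (6 binary) and personality (4 binary) auxiliary labels.

#' Read a JSONL corpus
#'
#' @param path Path to a line-delimited JSON file.
#' @return A `tc_corpus`: data.frame with columns id, text, label, split
#'   and, when present, emotion/personality label matrix columns
#'   (`emotion.1..6`, `personality.1..4`).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    label = vapply(recs, function(r) as.integer(r$label), integer(1)),
    split = vapply(recs, function(r)
      if (is.null(r$split)) NA_character_ else as.character(r$split),
      character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(recs[[1]]$emotion)) {
    df$emotion <- do.call(rbind, lapply(recs, function(r) as.integer(r$emotion)))
  }
  if (!is.null(recs[[1]]$personality)) {
    df$personality <- do.call(rbind, lapply(recs, function(r)
      as.integer(r$personality)))
  }
  class(df) <- c("tc_corpus", class(df))
  df
}

#' Write a corpus to JSONL
#'
#' @param corpus A `tc_corpus` data.frame.
#' @param path Output path.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(id = corpus$id[i], text = corpus$text[i],
                label = corpus$label[i])
    if (!is.na(corpus$split[i])) rec$split <- corpus$split[i]
    if (!is.null(corpus$emotion)) rec$emotion <- as.integer(corpus$emotion[i, ])
    if (!is.null(corpus$personality))
      rec$personality <- as.integer(corpus$personality[i, ])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
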