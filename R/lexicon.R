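# Lexicon container and the generic TSV dictionary format.
#
# Categorical lines:  word<TAB>category
# Norm lines:         word<TAB>norm_name<TAB>value
# '#' starts a comment; keys are case-folded; bigram keys ("two words")
# are allowed in categorical lexicons.

#' Lexicon slot names
#'
#' The seven dictionary slots backing the lexicon-based features: affective
#' norms (ANEW), its categorical extension (ANEW-Emo), the General Inquirer
#' (GI), the Geneva Affect Label Coder (GALC), LIWC-style psychological
#' categories, the NRC emotion lexicon (EmoLex) and SenticNet polarity
#' norms.
#'
#' @return Character vector of the seven slot names.
#' @export
lexicon_slots <- function() {
  c("ANEW", "ANEW-Emo", "GI", "GALC", "LIWC", "EmoLex", "SenticNet")
}

.tc_new_lexicon <- function(slot, categorical = list(), norms = list()) {
  structure(list(slot = slot, categorical = categorical, norms = norms),
            class = "tc_lexicon")
}

#' @export
print.tc_lexicon <- function(x, ...) {
  cat("<lexicon> slot=", x$slot,
      " categories=", length(x$categorical),
      " norms=", length(x$norms), "\n", sep = "")
  invisible(x)
}

#' Load a lexicon from the generic TSV dictionary format
#'
#' @param path Path to a TSV file (2 columns for categorical entries,
#'   3 columns for word norms; the two kinds may be mixed).
#' @param slot One of [lexicon_slots()].
#' @return A `tc_lexicon` with `categorical` (category -> word vector) and
#'   `norms` (norm name -> named numeric vector) maps.
#' @export
load_lexicon <- function(path, slot) {
  if (!slot %in% lexicon_slots()) {
    stop("unknown lexicon slot '", slot, "'; expected one of: ",
         paste(lexicon_slots(), collapse = ", "), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  categorical <- list()
  norms <- list()
  dup <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      word <- tolower(trimws(parts[1])); cat_ <- tolower(trimws(parts[2]))
      if (!nzchar(word) || !nzchar(cat_)) {
        stop("malformed categorical line ", i, " in ", path, call. = FALSE)
      }
      if (word %in% categorical[[cat_]]) dup <- dup + 1L else
        categorical[[cat_]] <- c(categorical[[cat_]], word)
    } else if (length(parts) == 3L) {
      word <- tolower(trimws(parts[1])); nm <- tolower(trimws(parts[2]))
      val <- suppressWarnings(as.numeric(parts[3]))
      if (!nzchar(word) || !nzchar(nm) || is.na(val)) {
        stop("malformed norm line ", i, " in ", path,
             ": non-numeric value or empty key", call. = FALSE)
      }
      norms[[nm]][word] <- val
    } else {
      stop("malformed line ", i, " in ", path,
           ": expected 2 or 3 tab-separated fields", call. = FALSE)
    }
  }
  if (dup > 0L) {
    warning(dup, " duplicate word/category pair(s) deduplicated in ", path,
            call. = FALSE)
  }
  .tc_new_lexicon(slot, categorical, norms)
}

#' Write a lexicon to the generic TSV dictionary format
#'
#' Writes a canonical form (sorted categories/norms, sorted words) so that
#' `write_lexicon(load_lexicon(x))` round-trips.
#'
#' @param lex A `tc_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "tc_lexicon"))
  out <- character(0)
  for (cat_ in sort(names(lex$categorical))) {
    for (w in sort(lex$categorical[[cat_]])) {
      out <- c(out, paste(w, cat_, sep = "\t"))
    }
  }
  for (nm in sort(names(lex$norms))) {
    v <- lex$norms[[nm]]
    for (w in sort(names(v))) {
      out <- c(out, paste(w, nm, format(v[[w]], digits = 15), sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Load register n-gram tables from TSV
#'
#' Format: `ngram<TAB>n<TAB>register<TAB>frequency<TAB>rank` with a header
#' line; n is 1 or 2 (bigram keys use a single space separator).
#'
#' @param path TSV path.
#' @return Named list register -> list(u = list(freq, rank), b = ...), the
#'   structure consumed by the stylistic feature scorers.
#' @export
load_register_tables <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ngram", "n", "register", "frequency", "rank")
  if (!all(need %in% names(df))) {
    stop("register table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (reg in unique(df$register)) {
    sub <- df[df$register == reg, , drop = FALSE]
    mk <- function(nn) {
      s <- sub[sub$n == nn, , drop = FALSE]
      list(freq = stats::setNames(s$frequency, tolower(s$ngram)),
           rank = stats::setNames(s$rank, tolower(s$ngram)))
    }
    out[[reg]] <- list(u = mk(1L), b = mk(2L))
  }
  out
}

#' Write register n-gram tables to TSV
#'
#' @param tables Structure as returned by [load_register_tables()].
#' @param path Output path.
#' @export
write_register_tables <- function(tables, path) {
  rows <- list()
  for (reg in names(tables)) {
    for (nn in c("u", "b")) {
      tb <- tables[[reg]][[nn]]
      if (!length(tb$freq)) next
      rows[[length(rows) + 1L]] <- data.frame(
        ngram = names(tb$freq), n = if (nn == "u") 1L else 2L,
        register = reg, frequency = unname(tb$freq),
        rank = unname(tb$rank[names(tb$freq)]), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
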