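# Deterministic text annotation: sentence splitting, tokenization, coarse POS
# tagging, rule lemmatization and syllable counting. The bundled "rules"
# backend has no external dependencies so every downstream result is
# bit-reproducible; an alternative backend can be registered at run time.

#' Coarse part-of-speech tag set
#'
#' The fixed 12-tag inventory used by the rule-based annotation backend.
#' Clause-level linguistic features only require coarse distinctions, so a
#' compact tag set keeps the fallback tagger auditable.
#'
#' @return Character vector of the 12 tags.
#' @export
pos_tagset <- function() {
  c("NOUN", "VERB", "AUX", "ADJ", "ADV", "PRON",
    "DET", "ADP", "CONJ", "NUM", "PUNCT", "OTHER")
}

# closed-class word lists (lowercase); order of lookup matters: the first
# list containing the word wins.
.tc_aux <- c("be", "am", "is", "are", "was", "were", "been", "being",
             "have", "has", "had", "having", "do", "does", "did",
             "will", "would", "shall", "should", "can", "could", "may",
             "might", "must", "ought",
             "'m", "'re", "'s", "'ve", "'ll", "'d")
.tc_pron <- c("i", "you", "he", "she", "it", "we", "they", "me", "him",
              "her", "us", "them", "my", "your", "his", "its", "our",
              "their", "mine", "yours", "hers", "ours", "theirs",
              "myself", "yourself", "himself", "herself", "itself",
              "ourselves", "yourselves", "themselves", "who", "whom",
              "whose", "someone", "anyone", "everyone", "something",
              "anything", "everything", "nothing", "somebody", "anybody",
              "everybody", "nobody")
.tc_det <- c("the", "a", "an", "this", "that", "these", "those", "some",
             "any", "no", "every", "each", "either", "neither", "both",
             "all", "most", "many", "much", "few", "several", "such",
             "what", "which")
.tc_adp <- c("in", "on", "at", "by", "for", "with", "about", "against",
             "between", "into", "through", "during", "before", "after",
             "above", "below", "to", "from", "up", "down", "of", "off",
             "over", "under", "near", "without", "within", "among",
             "across", "behind", "beyond", "around", "upon", "toward",
             "towards", "onto", "outside", "inside", "despite", "except",
             "per", "via")
.tc_conj <- c("and", "or", "but", "nor", "so", "yet", "because",
              "although", "though", "while", "if", "unless", "since",
              "whereas", "until", "whether")
.tc_neg <- c("not", "n't", "never")

# irregular verb forms -> lemma; doubles as an open-class VERB lookup for
# forms that carry no verbal suffix (ran, hid, ...).
.tc_irregular_verbs <- c(
  ran = "run", run = "run", hid = "hide", hidden = "hide", went = "go",
  gone = "go", goes = "go", got = "get", gotten = "get", said = "say",
  says = "say", made = "make", took = "take", taken = "take",
  came = "come", come = "come", saw = "see", seen = "see", knew = "know",
  known = "know", thought = "think", think = "think", felt = "feel",
  feel = "feel", found = "find", gave = "give", given = "give",
  told = "tell", kept = "keep", left = "leave", slept = "sleep",
  sleep = "sleep", woke = "wake", wake = "wake", sat = "sit", sit = "sit",
  stood = "stand", lost = "lose", met = "meet", paid = "pay",
  brought = "bring", began = "begin", begun = "begin", wrote = "write",
  written = "write", spoke = "speak", spoken = "speak", broke = "break",
  broken = "break", ate = "eat", eat = "eat", drank = "drink",
  drove = "drive", fell = "fall", fallen = "fall", grew = "grow",
  grown = "grow", held = "hold", heard = "hear", let = "let", put = "put",
  read = "read", sent = "send", sang = "sing", threw = "throw",
  thrown = "throw", understood = "understand", wore = "wear", won = "win",
  cried = "cry", cry = "cry", tried = "try", try = "try", worry = "worry",
  panic = "panic", sigh = "sigh", feels = "feel", ache = "ache")

# abbreviations that do NOT terminate a sentence when followed by a period
.tc_abbrev <- c("dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr", "no",
                "fig", "vs", "etc", "e.g", "i.e", "al", "inc", "dept",
                "approx", "est", "vol", "p", "pp")

#' Split text into sentences
#'
#' Rule-based splitter: a sentence ends at a run of `.`, `!` or `?`
#' (optionally followed by closing quotes/brackets) that is followed by
#' whitespace, unless the preceding word is on a bundled abbreviation list
#' (e.g. "Dr.", "e.g."). The concatenation of the returned strings equals
#' the input modulo whitespace.
#'
#' @param text A single UTF-8 character string (may be empty).
#' @return Character vector of sentence strings (zero-length for blank input).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  # candidate boundary positions: terminator run + optional closers, then space
  m <- gregexpr("[.!?]+[\"')\\]]*(?=\\s)", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(text)
  ends <- as.integer(m) + attr(m, "match.length") - 1L
  keep <- logical(length(ends))
  for (k in seq_along(ends)) {
    start <- as.integer(m)[k]
    # word immediately before the terminator
    prefix <- substr(text, max(1L, start - 12L), start - 1L)
    word <- regmatches(prefix, regexpr("[A-Za-z][A-Za-z.]*$", prefix))
    w <- if (length(word)) tolower(sub("\\.+$", "", word)) else ""
    is_abbrev <- w %in% .tc_abbrev ||
      (nchar(w) == 1L && grepl("^[a-z]$", w))  # single initials: "J. Smith"
    keep[k] <- !is_abbrev
  }
  ends <- ends[keep]
  if (!length(ends)) return(text)
  bounds <- c(0L, ends, nchar(text))
  bounds <- unique(bounds)
  out <- character(0)
  for (k in seq_len(length(bounds) - 1L)) {
    piece <- trimws(substr(text, bounds[k] + 1L, bounds[k + 1L]))
    if (nzchar(piece)) out <- c(out, piece)
  }
  out
}

#' Tokenize a sentence string
#'
#' Unicode word boundaries; contractions are split at the apostrophe
#' following treebank convention ("don't" -> "do", "n't"; "I'm" -> "I",
#' "'m"). Punctuation marks are their own tokens.
#'
#' @param sentence Character scalar.
#' @return Character vector of surface tokens.
#' @export
tokenize_words <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  pat <- "[[:alpha:]]+(?:'[[:alpha:]]+)*|[[:digit:]]+(?:[.,][[:digit:]]+)*|[^[:space:][:alnum:]]"
  raw <- regmatches(sentence, gregexpr(pat, sentence, perl = TRUE))[[1]]
  out <- character(0)
  for (tok in raw) {
    if (grepl("'", tok, fixed = TRUE) && grepl("[[:alpha:]]", tok)) {
      if (grepl("n't$", tok, ignore.case = TRUE)) {
        base <- substr(tok, 1L, nchar(tok) - 3L)
        if (nzchar(base)) out <- c(out, base)
        out <- c(out, substr(tok, nchar(tok) - 2L, nchar(tok)))
      } else {
        at <- regexpr("'", tok, fixed = TRUE)
        base <- substr(tok, 1L, at - 1L)
        rest <- substr(tok, at, nchar(tok))
        if (nzchar(base)) out <- c(out, base)
        if (nchar(rest) > 1L) out <- c(out, rest) else out <- c(out, rest)
      }
    } else {
      out <- c(out, tok)
    }
  }
  out
}

#' Count syllables in a word
#'
#' Deterministic vowel-group heuristic: the count is the number of maximal
#' vowel groups (aeiouy), minus one for a silent final "e" (not counted when
#' the word ends in consonant + "e", except a consonant + "le" ending which
#' keeps its syllable), floored at 1. Non-alphabetic input counts as 1.
#'
#' @param word Character scalar.
#' @return Integer >= 1.
#' @export
count_syllables <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  w <- tolower(gsub("[^a-z]", "", tolower(word)))
  if (!nzchar(w)) return(1L)
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  n <- if (groups[1] == -1L) 0L else length(groups)
  # silent final e: "-e" after a consonant, unless "-le" after a consonant
  if (n > 1L || (n == 1L && grepl("[aeiouy]", substr(w, 1, nchar(w) - 1L)))) {
    if (grepl("[^aeiouy]e$", w) && !grepl("[^aeiouy]le$", w)) n <- n - 1L
  } else if (n == 1L && grepl("[^aeiouy]e$", w)) {
    n <- n - 1L  # e.g. "the": lone vowel group is the silent e
  }
  max(n, 1L)
}

.tc_tag_word <- function(surface) {
  w <- tolower(surface)
  if (!grepl("[[:alnum:]]", surface)) return("PUNCT")
  if (grepl("^[[:digit:]]", surface)) return("NUM")
  if (w %in% .tc_aux) return("AUX")
  if (w %in% .tc_pron) return("PRON")
  if (w %in% .tc_det) return("DET")
  if (w %in% .tc_adp) return("ADP")
  if (w %in% .tc_conj) return("CONJ")
  if (w %in% .tc_neg) return("ADV")
  if (w %in% names(.tc_irregular_verbs)) return("VERB")
  if (grepl("ly$", w) && nchar(w) > 3L) return("ADV")
  if (grepl("(ous|ful|ive|able|ible|ical|less|ish|ary)$", w)) return("ADJ")
  if (grepl("(ize|ise|ify|ing|ed)$", w) && nchar(w) > 4L) return("VERB")
  "NOUN"
}

.tc_lemma <- function(surface, pos) {
  w <- tolower(surface)
  if (pos == "PUNCT" || pos == "NUM") return(w)
  if (w %in% names(.tc_irregular_verbs)) return(unname(.tc_irregular_verbs[w]))
  undouble <- function(x) {
    n <- nchar(x)
    if (n >= 3L && substr(x, n, n) == substr(x, n - 1L, n - 1L) &&
        grepl("[^aeiouyls]", substr(x, n, n))) substr(x, 1L, n - 1L) else x
  }
  if (pos == "VERB") {
    if (grepl("ing$", w) && nchar(w) > 5L) return(undouble(substr(w, 1L, nchar(w) - 3L)))
    if (grepl("ied$", w) && nchar(w) > 4L) return(paste0(substr(w, 1L, nchar(w) - 3L), "y"))
    if (grepl("ed$", w) && nchar(w) > 4L) return(undouble(substr(w, 1L, nchar(w) - 2L)))
  }
  if (pos %in% c("NOUN", "VERB")) {
    if (grepl("ies$", w) && nchar(w) > 4L) return(paste0(substr(w, 1L, nchar(w) - 3L), "y"))
    if (grepl("(ses|xes|zes|ches|shes)$", w)) return(substr(w, 1L, nchar(w) - 2L))
    if (grepl("s$", w) && !grepl("(ss|us|is)$", w) && nchar(w) > 3L)
      return(substr(w, 1L, nchar(w) - 1L))
  }
  w
}

.tc_annotate_sentence <- function(sentence) {
  surfaces <- tokenize_words(sentence)
  if (!length(surfaces)) return(NULL)
  pos <- vapply(surfaces, .tc_tag_word, character(1), USE.NAMES = FALSE)
  lemma <- mapply(.tc_lemma, surfaces, pos, USE.NAMES = FALSE)
  syll <- vapply(surfaces, count_syllables, integer(1), USE.NAMES = FALSE)
  is_content <- pos %in% c("NOUN", "VERB", "ADJ", "ADV")
  prev <- c("", tolower(surfaces[-length(surfaces)]))
  prev_pos <- c("", pos[-length(pos)])
  is_finite <- pos %in% c("VERB", "AUX") &
    prev != "to" &
    !grepl("ing$", tolower(surfaces)) &
    !(grepl("ed$", tolower(surfaces)) & prev_pos == "AUX")
  data.frame(surface = surfaces, lemma = lemma, pos = pos,
             is_content = is_content, is_finite_verb = is_finite,
             syllables = syll, stringsAsFactors = FALSE)
}

# backend registry -----------------------------------------------------------

.tc_backends <- new.env(parent = emptyenv())

#' Register an annotation backend
#'
#' A backend is a function `function(text) -> list of sentence token
#' data.frames` with the same column contract as the bundled "rules"
#' backend.
#'
#' @param name Backend identifier.
#' @param fn Backend function.
#' @export
register_annotation_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .tc_backends)
  invisible(name)
}

#' List registered annotation backends
#' @return Character vector of backend names.
#' @export
annotation_backends <- function() sort(ls(.tc_backends))

.tc_rules_backend <- function(text) {
  sents <- split_sentences(text)
  out <- lapply(sents, .tc_annotate_sentence)
  out[!vapply(out, is.null, logical(1))]
}

#' Annotate a text
#'
#' Produces an `annotated_text`: an ordered list of sentences, each a
#' data.frame of tokens with surface form, lemma, coarse POS tag, content
#' and finite-verb flags and syllable count. The default "rules" backend is
#' deterministic and dependency-free.
#'
#' @param text Character scalar (raw post text).
#' @param doc_id Document identifier.
#' @param backend Backend name (default "rules").
#' @return An object of class `annotated_text` with fields `doc_id`,
#'   `sentences` and `n_sentences`.
#' @export
annotate <- function(text, doc_id = "doc", backend = "rules") {
  if (!backend %in% annotation_backends()) {
    stop("unknown annotation backend '", backend, "'; available: ",
         paste(annotation_backends(), collapse = ", "), call. = FALSE)
  }
  fn <- get(backend, envir = .tc_backends)
  sentences <- fn(text)
  structure(list(doc_id = doc_id, sentences = sentences,
                 n_sentences = length(sentences)),
            class = "annotated_text")
}

#' @export
print.annotated_text <- function(x, ...) {
  cat("<annotated_text> ", x$doc_id, ": ", x$n_sentences, " sentence(s), ",
      sum(vapply(x$sentences, nrow, integer(1))), " token(s)\n", sep = "")
  invisible(x)
}

#' Serialize an annotated text to JSON
#'
#' @param doc An `annotated_text`.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
annotated_to_json <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "annotated_text"))
  js <- jsonlite::toJSON(list(doc_id = doc$doc_id, sentences = doc$sentences),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize an annotated text from JSON
#'
#' @param json JSON string or file path produced by [annotated_to_json()].
#' @return An `annotated_text`.
#' @export
annotated_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  sentences <- lapply(x$sentences, function(s) {
    data.frame(surface = unlist(s$surface),
               lemma = unlist(s$lemma),
               pos = unlist(s$pos),
               is_content = as.logical(unlist(s$is_content)),
               is_finite_verb = as.logical(unlist(s$is_finite_verb)),
               syllables = as.integer(unlist(s$syllables)),
               stringsAsFactors = FALSE)
  })
  structure(list(doc_id = x$doc_id, sentences = sentences,
                 n_sentences = length(sentences)),
            class = "annotated_text")
}

# register the bundled backend at load time
.onLoad <- function(libname, pkgname) {
  register_annotation_backend("rules", .tc_rules_backend)
}
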