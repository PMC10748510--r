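# The feature registry: the enumerable catalogue of 498 feature
# definitions — 192 general linguistic features (GLFs) in five groups and
# 306 lexicon-based features (LBFs) over seven dictionary slots. Group and
# slot sizes are fixed constraints of the framework; the per-feature
# composition inside each group is the package's documented default.

.tc_liwc_categories <- c(
  "function", "pronoun", "ppron", "i", "we", "you", "shehe", "they",
  "ipron", "article", "prep", "auxverb", "adverb", "conj", "negate",
  "verb", "adj", "compare", "interrog", "number", "quant",
  "affect", "posemo", "negemo", "anx", "anger", "sad",
  "social", "family", "friend", "female", "male",
  "cogproc", "insight", "cause", "discrep", "tentat", "certain", "differ",
  "percept", "see", "hear", "feel",
  "bio", "body", "health", "sexual", "ingest",
  "drives", "affiliation", "achieve", "power", "reward", "risk",
  "focuspast", "focuspresent", "focusfuture",
  "relativ", "motion", "space", "time", "work", "leisure", "home")

.tc_galc_categories <- c(
  "admiration", "amusement", "anger", "anxiety", "being_touched",
  "boredom", "compassion", "contempt", "contentment", "desperation",
  "disappointment", "disgust", "dissatisfaction", "envy", "fear",
  "feeling_love", "gratitude", "guilt", "happiness", "hatred", "hope",
  "humility", "interest", "irritation", "jealousy", "joy", "longing",
  "lust", "pleasure", "pride", "relaxation", "relief", "sadness",
  "shame", "surprise", "tension", "positive_general", "negative_general")

.tc_gi_categories <- c(
  "positiv", "negativ", "pstv", "ngtv", "strong", "weak", "active",
  "passive", "pleasur", "pain", "feel", "arousal", "emot", "virtue",
  sprintf("gi_%03d", 15:178))

.tc_emolex_categories <- c(
  "anger", "anticipation", "disgust", "fear", "joy", "sadness",
  "surprise", "trust", "positive", "negative")

.tc_anew_norms <- c("valence", "arousal", "dominance", "pleasure",
                    "imagery", "familiarity")
.tc_anewemo_categories <- c("happiness", "sadness", "fear", "disgust",
                            "anger")
.tc_senticnet_norms <- c("polarity", "pleasantness", "attention",
                         "sensitivity", "aptitude")

# slot -> list(type, keys); ordering fixes LBF feature ids
.tc_lbf_catalogue <- function() {
  list(
    "ANEW" = list(type = "norm", keys = .tc_anew_norms),
    "ANEW-Emo" = list(type = "category", keys = .tc_anewemo_categories),
    "GI" = list(type = "category", keys = .tc_gi_categories),
    "GALC" = list(type = "category", keys = .tc_galc_categories),
    "LIWC" = list(type = "category", keys = .tc_liwc_categories),
    "EmoLex" = list(type = "category", keys = .tc_emolex_categories),
    "SenticNet" = list(type = "norm", keys = .tc_senticnet_norms)
  )
}

#' Default feature registry
#'
#' Enumerates the full default catalogue: 192 GLFs (morphosyntactic 48,
#' lexical 45, readability 13, cohesion 30, stylistic 56) and 306 LBFs over
#' the seven lexicon slots (ANEW 6 norms, ANEW-Emo 5 categories, GI 178,
#' GALC 38, LIWC 64, EmoLex 10, SenticNet 5 norms). Every entry resolves to
#' a scorer: GLFs to closures over window statistics, LBFs to a
#' (slot, type, key) triple evaluated against loaded lexicons.
#'
#' @return An object of class `feature_registry` with elements `glf` and
#'   `lbf` (spec data frames), `glf_scorers` (named list, registry order)
#'   and `glf_group_sizes`.
#' @export
default_registry <- function() {
  groups <- .tc_all_glf_scorers()
  glf_names <- character(0)
  glf_groups <- character(0)
  scorers <- list()
  for (g in names(groups)) {
    nm <- names(groups[[g]])
    glf_names <- c(glf_names, nm)
    glf_groups <- c(glf_groups, rep(g, length(nm)))
    scorers <- c(scorers, groups[[g]])
  }
  stopifnot(!anyDuplicated(glf_names))
  glf <- data.frame(
    feature_id = seq_along(glf_names), name = glf_names, family = "GLF",
    group = glf_groups, kind = "dense", stringsAsFactors = FALSE)

  cat_ <- .tc_lbf_catalogue()
  lbf_rows <- list()
  for (slot in names(cat_)) {
    spec <- cat_[[slot]]
    lbf_rows[[slot]] <- data.frame(
      name = paste0(gsub("-", "_", tolower(slot)), "_", spec$keys),
      family = "LBF", group = slot, kind = "sparse", type = spec$type,
      key = spec$keys, stringsAsFactors = FALSE)
  }
  lbf <- do.call(rbind, lbf_rows)
  rownames(lbf) <- NULL
  lbf <- cbind(feature_id = seq_len(nrow(lbf)), lbf)

  structure(list(glf = glf, lbf = lbf, glf_scorers = scorers,
                 glf_group_sizes = vapply(groups, length, integer(1))),
            class = "feature_registry")
}

#' @export
print.feature_registry <- function(x, ...) {
  cat("<feature_registry> ", nrow(x$glf), " GLF + ", nrow(x$lbf),
      " LBF = ", nrow(x$glf) + nrow(x$lbf), " features\n", sep = "")
  cat("  GLF groups: ",
      paste(names(x$glf_group_sizes), x$glf_group_sizes,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  LBF slots:  ",
      paste(names(table(x$lbf$group)[unique(x$lbf$group)]),
            as.integer(table(x$lbf$group)[unique(x$lbf$group)]),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
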