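# General linguistic feature (GLF) scorers. Every scorer maps a window
# statistics object to a single finite real. The catalogue is organised in
# five groups: morphosyntactic complexity, lexical richness, readability,
# cohesion and register stylistics. All divisions are guarded so degenerate
# windows (single short sentence) yield finite floors rather than NaN.

.tc_subordinators <- c("because", "although", "though", "while", "if",
                       "unless", "since", "whereas", "until", "whether")
.tc_coordinators <- c("and", "or", "but", "nor", "so", "yet")
.tc_connectives <- list(
  additive = c("and", "also", "moreover", "furthermore", "besides", "too"),
  adversative = c("but", "however", "although", "though", "yet",
                  "nevertheless", "whereas", "instead"),
  causal = c("because", "so", "therefore", "thus", "since", "hence",
             "consequently"),
  temporal = c("then", "when", "while", "after", "before", "until",
               "finally", "meanwhile", "now"))

.tc_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) 0 else length(intersect(a, b)) / u
}
.tc_containment <- function(a, b) {
  if (length(a) == 0L) 0 else length(intersect(a, b)) / length(a)
}
.tc_dice <- function(a, b) {
  s <- length(a) + length(b)
  if (s == 0L) 0 else 2 * length(intersect(a, b)) / s
}

.tc_lemma_sets <- function(tok) {
  if (is.null(tok) || !nrow(tok)) {
    empty <- character(0)
    return(list(all = empty, content = empty, noun = empty, verb = empty,
                adj = empty, adv = empty, pron = empty, fun = empty,
                bigrams = empty))
  }
  words <- tok[tok$pos != "PUNCT", , drop = FALSE]
  surf <- tolower(words$surface)
  bi <- if (length(surf) > 1L) paste(surf[-length(surf)], surf[-1L]) else character(0)
  list(all = unique(words$lemma),
       content = unique(words$lemma[words$is_content]),
       noun = unique(words$lemma[words$pos == "NOUN"]),
       verb = unique(words$lemma[words$pos %in% c("VERB", "AUX")]),
       adj = unique(words$lemma[words$pos == "ADJ"]),
       adv = unique(words$lemma[words$pos == "ADV"]),
       pron = unique(words$lemma[words$pos == "PRON"]),
       fun = unique(words$lemma[!words$is_content]),
       bigrams = unique(bi))
}

# Build the statistics object every GLF scorer consumes.
# sentences: list of token data.frames (the window); prev1/prev2: the one/two
# sentences preceding the window; prev_all: all earlier sentences combined.
build_window_stats <- function(sentences, prev1 = NULL, prev2 = NULL,
                               prev_all = NULL, resources = NULL) {
  tok <- if (length(sentences)) do.call(rbind, sentences) else
    data.frame(surface = character(0), lemma = character(0),
               pos = character(0), is_content = logical(0),
               is_finite_verb = logical(0), syllables = integer(0))
  words <- tok[tok$pos != "PUNCT", , drop = FALSE]
  tags <- vapply(pos_tagset(), function(tg) sum(tok$pos == tg), numeric(1))
  surf <- tolower(words$surface)
  bigrams <- unlist(lapply(sentences, function(s) {
    w <- tolower(s$surface[s$pos != "PUNCT"])
    if (length(w) > 1L) paste(w[-length(w)], w[-1L]) else character(0)
  }))
  list(
    n_sent = length(sentences),
    tok = tok, words = words,
    n_tok = nrow(tok), n_words = nrow(words),
    n_chars = sum(nchar(words$surface)),
    n_syll = sum(words$syllables),
    tags = tags,
    finite = sum(tok$is_finite_verb),
    surfaces = surf,
    lemmas = words$lemma,
    content_lemmas = words$lemma[words$is_content],
    word_lengths = nchar(words$surface),
    word_sylls = words$syllables,
    sent_tok_counts = vapply(sentences, nrow, integer(1)),
    first_words = vapply(sentences, function(s) {
      w <- s$surface[s$pos != "PUNCT"]
      if (length(w)) tolower(w[1L]) else ""
    }, character(1)),
    bigrams = bigrams,
    sets = .tc_lemma_sets(tok),
    sent_sets = lapply(sentences, .tc_lemma_sets),
    prev1 = .tc_lemma_sets(prev1),
    prev2 = .tc_lemma_sets(prev2),
    prev_all_content = if (is.null(prev_all)) character(0) else
      unique(prev_all$lemma[prev_all$is_content & prev_all$pos != "PUNCT"]),
    resources = resources
  )
}

.tc_div <- function(num, den) if (den <= 0) 0 else num / den

# --- morphosyntactic group (48 scorers) -------------------------------------

.tc_morpho_scorers <- function() {
  sc <- list(
    mean_sent_len_tokens = function(st) .tc_div(st$n_tok, st$n_sent),
    mean_sent_len_words = function(st) .tc_div(st$n_words, st$n_sent),
    mean_sent_len_chars = function(st) .tc_div(st$n_chars, st$n_sent),
    mean_clause_len_words = function(st) st$n_words / max(st$finite, 1),
    clauses_per_sentence = function(st) .tc_div(st$finite, st$n_sent)
  )
  for (tg in pos_tagset()) {
    local({
      tag <- tg
      sc[[paste0("prop_", tolower(tag))]] <<-
        function(st) .tc_div(st$tags[[tag]], st$n_tok)
      sc[[paste0("per_sent_", tolower(tag))]] <<-
        function(st) .tc_div(st$tags[[tag]], st$n_sent)
    })
  }
  sc$pos_entropy <- function(st) {
    p <- st$tags / max(st$n_tok, 1)
    p <- p[p > 0]
    if (!length(p)) 0 else -sum(p * log(p))
  }
  ratio <- function(a, b) function(st) {
    (sum(st$tags[a]) + 1) / (sum(st$tags[b]) + 1)
  }
  sc$noun_verb_ratio <- ratio("NOUN", c("VERB", "AUX"))
  sc$adj_noun_ratio <- ratio("ADJ", "NOUN")
  sc$adv_verb_ratio <- ratio("ADV", c("VERB", "AUX"))
  sc$pron_noun_ratio <- ratio("PRON", "NOUN")
  sc$det_noun_ratio <- ratio("DET", "NOUN")
  sc$aux_verb_ratio <- ratio("AUX", "VERB")
  sc$content_function_ratio <- function(st) {
    (sum(st$words$is_content) + 1) / (sum(!st$words$is_content) + 1)
  }
  sc$finite_verb_prop <- function(st) .tc_div(st$finite, st$n_words)
  sc$subordinator_rate <- function(st)
    .tc_div(sum(st$surfaces %in% .tc_subordinators), st$n_words)
  sc$coordinator_rate <- function(st)
    .tc_div(sum(st$surfaces %in% .tc_coordinators), st$n_words)
  pairs <- list(det_noun = c("DET", "NOUN"), adj_noun = c("ADJ", "NOUN"),
                noun_verb = c("NOUN", "VERB"), pron_verb = c("PRON", "VERB"),
                pron_aux = c("PRON", "AUX"), adp_det = c("ADP", "DET"),
                aux_verb = c("AUX", "VERB"), verb_adv = c("VERB", "ADV"))
  for (nm in names(pairs)) {
    local({
      pr <- pairs[[nm]]
      sc[[paste0("bigram_", nm)]] <<- function(st) {
        if (st$n_tok < 2L) return(0)
        p <- st$tok$pos
        .tc_div(sum(p[-length(p)] == pr[1] & p[-1L] == pr[2]), st$n_tok - 1L)
      }
    })
  }
  sc
}

# --- lexical richness group (45 scorers) ------------------------------------

.tc_seg_ttr <- function(lemmas, size) {
  n <- length(lemmas)
  if (n == 0L) return(0)
  starts <- seq(1L, n, by = size)
  mean(vapply(starts, function(s) {
    seg <- lemmas[s:min(s + size - 1L, n)]
    length(unique(seg)) / length(seg)
  }, numeric(1)))
}

.tc_lexical_scorers <- function() {
  sc <- list(
    ttr = function(st) .tc_div(length(unique(st$lemmas)), st$n_words),
    root_ttr = function(st)
      if (st$n_words == 0L) 0 else length(unique(st$lemmas)) / sqrt(st$n_words),
    log_ttr = function(st) {
      n <- st$n_words; v <- length(unique(st$lemmas))
      if (n <= 1L || v <= 1L) 0 else log(v) / log(n)
    },
    maas = function(st) {
      n <- st$n_words; v <- length(unique(st$lemmas))
      if (n <= 1L || v < 1L) 0 else (log(n) - log(v)) / log(n)^2
    },
    uber = function(st) {
      n <- st$n_words; v <- length(unique(st$lemmas))
      if (n <= 1L || v <= 1L || n == v) 0 else log(n)^2 / (log(n) - log(v))
    }
  )
  classes <- c(noun = "NOUN", verb = "VERB", adj = "ADJ", adv = "ADV")
  for (nm in names(classes)) {
    local({
      tag <- classes[[nm]]
      sc[[paste0("ttr_", nm)]] <<- function(st) {
        lem <- st$words$lemma[st$words$pos == tag]
        .tc_div(length(unique(lem)), length(lem))
      }
      sc[[paste0("density_", nm)]] <<- function(st)
        .tc_div(sum(st$words$pos == tag), st$n_words)
      sc[[paste0("mean_len_", nm)]] <<- function(st) {
        x <- nchar(st$words$surface[st$words$pos == tag])
        if (length(x)) mean(x) else 0
      }
      sc[[paste0("mean_syll_", nm)]] <<- function(st) {
        x <- st$words$syllables[st$words$pos == tag]
        if (length(x)) mean(x) else 0
      }
    })
  }
  sc$lexical_density <- function(st) .tc_div(sum(st$words$is_content), st$n_words)
  sc$function_word_density <- function(st)
    .tc_div(sum(!st$words$is_content), st$n_words)
  sc$mean_word_length <- function(st)
    if (st$n_words == 0L) 0 else mean(st$word_lengths)
  sc$mean_word_syllables <- function(st)
    if (st$n_words == 0L) 0 else mean(st$word_sylls)
  sc$mean_lemma_length <- function(st)
    if (st$n_words == 0L) 0 else mean(nchar(st$lemmas))
  for (k in c(5L, 6L, 7L, 8L, 10L)) {
    local({
      kk <- k
      sc[[paste0("prop_words_ge_", kk, "ch")]] <<- function(st)
        if (st$n_words == 0L) 0 else mean(st$word_lengths >= kk)
    })
  }
  for (k in c(2L, 3L, 4L)) {
    local({
      kk <- k
      sc[[paste0("prop_words_ge_", kk, "syll")]] <<- function(st)
        if (st$n_words == 0L) 0 else mean(st$word_sylls >= kk)
    })
  }
  sc$hapax_proportion <- function(st) {
    if (st$n_words == 0L) return(0)
    tab <- table(st$lemmas)
    sum(tab == 1L) / st$n_words
  }
  sc$inflectional_diversity <- function(st) {
    v <- length(unique(st$lemmas))
    if (v == 0L) 0 else length(unique(st$surfaces)) / v
  }
  sc$mean_log_unigram_freq <- function(st) {
    f <- .tc_register_freqs(st, "u", average = TRUE)
    if (!length(f)) 0 else mean(log1p(f))
  }
  sc$rare_word_rate <- function(st) {
    f <- .tc_register_freqs(st, "u", average = TRUE)
    if (!length(f)) 0 else mean(f == 0)
  }
  for (s in c(5L, 10L, 15L, 20L)) {
    local({
      ss <- s
      sc[[paste0("msttr_", ss)]] <<- function(st) .tc_seg_ttr(st$lemmas, ss)
    })
  }
  sc$prop_long_content <- function(st) {
    x <- nchar(st$words$surface[st$words$is_content])
    if (length(x)) mean(x >= 7L) else 0
  }
  sc$mean_content_word_length <- function(st) {
    x <- nchar(st$words$surface[st$words$is_content])
    if (length(x)) mean(x) else 0
  }
  sc$punctuation_rate <- function(st) .tc_div(st$tags[["PUNCT"]], st$n_tok)
  sc
}

# --- readability group (13 scorers) -----------------------------------------

.tc_readability_scorers <- function() {
  W <- function(st) max(st$n_words, 1)
  S <- function(st) max(st$n_sent, 1)
  list(
    flesch_reading_ease = function(st)
      206.835 - 1.015 * (W(st) / S(st)) - 84.6 * (st$n_syll / W(st)),
    flesch_kincaid_grade = function(st)
      0.39 * (W(st) / S(st)) + 11.8 * (st$n_syll / W(st)) - 15.59,
    gunning_fog = function(st) {
      complex <- sum(st$word_sylls >= 3L)
      0.4 * (W(st) / S(st) + 100 * complex / W(st))
    },
    smog = function(st) {
      complex <- sum(st$word_sylls >= 3L)
      1.0430 * sqrt(complex * 30 / S(st)) + 3.1291
    },
    ari = function(st)
      4.71 * (st$n_chars / W(st)) + 0.5 * (W(st) / S(st)) - 21.43,
    coleman_liau = function(st)
      0.0588 * (100 * st$n_chars / W(st)) - 0.296 * (100 * S(st) / W(st)) - 15.8,
    lix = function(st) {
      long6 <- sum(st$word_lengths > 6L)
      W(st) / S(st) + 100 * long6 / W(st)
    },
    rix = function(st) sum(st$word_lengths > 6L) / S(st),
    dale_chall = function(st) {
      easy <- .tc_easy_words(st)
      hard <- sum(!(tolower(st$lemmas) %in% easy))
      pct <- 100 * hard / W(st)
      out <- 0.1579 * pct + 0.0496 * (W(st) / S(st))
      if (pct > 5) out <- out + 3.6365
      out
    },
    linsear_write = function(st) {
      easy <- sum(st$word_sylls <= 2L)
      hard <- sum(st$word_sylls >= 3L)
      r <- (easy + 3 * hard) / S(st)
      if (r > 20) r / 2 else r / 2 - 1
    },
    forcast = function(st) {
      mono <- sum(st$word_sylls == 1L)
      20 - (mono / W(st) * 150) / 10
    },
    strain_index = function(st) (st$n_syll / S(st)) * 3 / 10,
    spache = function(st) {
      easy <- .tc_easy_words(st)
      hard <- sum(!(tolower(st$lemmas) %in% easy))
      0.141 * (W(st) / S(st)) + 0.086 * (100 * hard / W(st)) + 0.839
    }
  )
}

.tc_easy_words <- function(st) {
  res <- st$resources
  if (!is.null(res) && !is.null(res$easy_words)) return(res$easy_words)
  default_easy_words()
}

#' Default familiar-word list
#'
#' A compact stand-in for the long familiar-word lists used by vocabulary
#' based readability formulas (Dale-Chall, Spache): all closed-class words
#' of the rules tagger plus the lemmas of its irregular-verb table and a
#' set of very common nouns and adjectives.
#'
#' @return Lowercase character vector.
#' @export
default_easy_words <- function() {
  unique(c(.tc_aux, .tc_pron, .tc_det, .tc_adp, .tc_conj, .tc_neg,
           names(.tc_irregular_verbs), unname(.tc_irregular_verbs),
           c("cat", "dog", "man", "woman", "boy", "girl", "day", "night",
             "time", "year", "home", "house", "work", "life", "hand",
             "eye", "head", "friend", "mother", "father", "good", "bad",
             "big", "small", "old", "new", "long", "little", "own",
             "other", "great", "high", "different", "same", "right",
             "left", "sun", "moon", "water", "food", "book", "school",
             "road", "tree", "bird", "fish", "door", "window", "table",
             "chair", "bed", "room", "wall", "floor", "city", "town",
             "rain", "snow", "wind", "fire", "light", "dark", "warm",
             "cold", "hot", "run", "walk", "talk", "look", "mat", "hat")))
}

# --- cohesion group (30 scorers) --------------------------------------------

.tc_cohesion_scorers <- function() {
  ov <- function(slot, fn) function(st) fn(st$sets[[slot]], st$prev1[[slot]])
  sc <- list(
    adj_overlap_content = ov("content", .tc_jaccard),
    adj_overlap_all = ov("all", .tc_jaccard),
    adj_overlap_nouns = ov("noun", .tc_jaccard),
    adj_overlap_verbs = ov("verb", .tc_jaccard),
    adj_overlap_adj = ov("adj", .tc_jaccard),
    adj_overlap_adv = ov("adv", .tc_jaccard),
    adj_overlap_pron = ov("pron", .tc_jaccard),
    adj_containment_content = ov("content", .tc_containment),
    adj_containment_all = ov("all", .tc_containment),
    adj_containment_nouns = ov("noun", .tc_containment),
    adj_containment_verbs = ov("verb", .tc_containment),
    adj_dice_content = ov("content", .tc_dice),
    adj_overlap_function = ov("fun", .tc_jaccard),
    adj_bigram_overlap = ov("bigrams", .tc_jaccard),
    lag2_overlap_content = function(st) .tc_jaccard(st$sets$content, st$prev2$content),
    lag2_overlap_all = function(st) .tc_jaccard(st$sets$all, st$prev2$all),
    lag2_overlap_nouns = function(st) .tc_jaccard(st$sets$noun, st$prev2$noun),
    cumulative_overlap_content = function(st)
      .tc_containment(st$sets$content, st$prev_all_content),
    connective_rate_all = function(st)
      .tc_div(sum(st$surfaces %in% unique(unlist(.tc_connectives))), st$n_words),
    repeated_lemma_ratio = function(st)
      if (st$n_words == 0L) 0 else 1 - length(unique(st$lemmas)) / st$n_words,
    repeated_content_ratio = function(st) {
      n <- length(st$content_lemmas)
      if (n == 0L) 0 else 1 - length(unique(st$content_lemmas)) / n
    },
    definite_article_rate = function(st) .tc_div(sum(st$surfaces == "the"), st$n_words),
    demonstrative_rate = function(st)
      .tc_div(sum(st$surfaces %in% c("this", "that", "these", "those")), st$n_words),
    pronoun_density = function(st) .tc_div(st$tags[["PRON"]], st$n_words),
    sentence_initial_connective_prop = function(st) {
      if (st$n_sent == 0L) return(0)
      mean(st$first_words %in% unique(unlist(.tc_connectives)))
    },
    within_window_adjacent_overlap = function(st) {
      if (st$n_sent < 2L) return(0)
      vals <- vapply(seq_len(st$n_sent - 1L), function(i) {
        .tc_jaccard(st$sent_sets[[i + 1L]]$content, st$sent_sets[[i]]$content)
      }, numeric(1))
      mean(vals)
    }
  )
  for (nm in names(.tc_connectives)) {
    local({
      words <- .tc_connectives[[nm]]
      sc[[paste0("connective_rate_", nm)]] <<- function(st)
        .tc_div(sum(st$surfaces %in% words), st$n_words)
    })
  }
  sc
}

# --- stylistic group (56 scorers) -------------------------------------------

#' Register names of the bundled register n-gram tables
#' @return Character vector of the four register names.
#' @export
register_names <- function() c("blog", "news", "fiction", "academic")

.tc_register_freqs <- function(st, which = "u", average = FALSE,
                               register = NULL) {
  res <- st$resources
  grams <- if (which == "u") st$surfaces else st$bigrams
  if (is.null(res) || is.null(res$register_tables) || !length(grams))
    return(numeric(0))
  tabs <- res$register_tables
  regs <- if (is.null(register)) names(tabs) else register
  mat <- vapply(regs, function(r) {
    tb <- tabs[[r]][[which]]
    f <- tb$freq[grams]
    f[is.na(f)] <- 0
    f
  }, numeric(length(grams)))
  if (length(grams) == 1L) mat <- matrix(mat, nrow = 1L)
  if (average) rowMeans(mat) else mat
}

.tc_register_ranks <- function(st, which, register) {
  res <- st$resources
  grams <- if (which == "u") st$surfaces else st$bigrams
  if (is.null(res) || is.null(res$register_tables) || !length(grams))
    return(list(ranks = numeric(0), max_rank = 1))
  tb <- res$register_tables[[register]][[which]]
  mr <- max(tb$rank, 1)
  rk <- tb$rank[grams]
  rk[is.na(rk)] <- mr + 1
  list(ranks = rk, max_rank = mr)
}

.tc_stylistic_scorers <- function() {
  sc <- list()
  for (reg in register_names()) {
    for (n in c("u", "b")) {
      local({
        rg <- reg; nn <- n
        tag <- paste0(rg, "_", if (nn == "u") "uni" else "bi")
        sc[[paste0(tag, "_mean_log_freq")]] <<- function(st) {
          f <- .tc_register_freqs(st, nn, register = rg)
          if (!length(f)) 0 else mean(log1p(f))
        }
        sc[[paste0(tag, "_sd_log_freq")]] <<- function(st) {
          f <- .tc_register_freqs(st, nn, register = rg)
          if (length(f) < 2L) 0 else stats::sd(log1p(f))
        }
        sc[[paste0(tag, "_max_log_freq")]] <<- function(st) {
          f <- .tc_register_freqs(st, nn, register = rg)
          if (!length(f)) 0 else max(log1p(f))
        }
        sc[[paste0(tag, "_oov_rate")]] <<- function(st) {
          f <- .tc_register_freqs(st, nn, register = rg)
          if (!length(f)) 0 else mean(f == 0)
        }
        sc[[paste0(tag, "_mean_log_rank")]] <<- function(st) {
          r <- .tc_register_ranks(st, nn, rg)
          if (!length(r$ranks)) 0 else mean(log(r$ranks))
        }
        sc[[paste0(tag, "_median_log_rank")]] <<- function(st) {
          r <- .tc_register_ranks(st, nn, rg)
          if (!length(r$ranks)) 0 else stats::median(log(r$ranks))
        }
        sc[[paste0(tag, "_top_quartile_prop")]] <<- function(st) {
          r <- .tc_register_ranks(st, nn, rg)
          if (!length(r$ranks)) 0 else mean(r$ranks <= r$max_rank / 4)
        }
      })
    }
  }
  sc
}

# Assemble all GLF scorers in registry order.
.tc_all_glf_scorers <- function() {
  groups <- list(
    morphosyntactic = .tc_morpho_scorers(),
    lexical = .tc_lexical_scorers(),
    readability = .tc_readability_scorers(),
    cohesion = .tc_cohesion_scorers(),
    stylistic = .tc_stylistic_scorers()
  )
  groups
}
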