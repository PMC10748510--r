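# Synthetic-corpus generator. Emulates the statistical structure the
# analysis assumes — binary condition labels, per-class shifts in a planted
# GLF group, planted lexicon-word usage rates, and auxiliary emotion (6
# Ekman) and personality (4 MBTI) labels with a specified phi/Pearson
# correlation to the condition label — over a closed synthetic vocabulary
# whose word lengths and syllable counts are controlled, so feature-level
# ground truth is computable by hand. Everything is deterministic under the
# config seed.

#' Generator configuration
#'
#' @param n_docs Number of documents (default 400).
#' @param class_balance P(case) (default 0.5).
#' @param mean_sentences Poisson mean of sentences per document (default 8;
#'   a short social-media-style post).
#' @param mean_sentence_len,sd_sentence_len Gaussian parameters for content
#'   tokens per sentence (defaults 10 and 3).
#' @param planted_group GLF group carrying the class signal:
#'   "morphosyntactic" (cases' sentence lengths shifted by `effect_size`
#'   standard deviations) or "stylistic" (cases draw words from the
#'   high-register-frequency half of the vocabulary with log-odds
#'   `effect_size`) or "none".
#' @param effect_size Standardized mean shift d (default 2, a strong
#'   planted signal).
#' @param p_case,p_control Per-slot emission rates of planted lexicon words
#'   for case and control documents (defaults 0.3 and 0.05).
#' @param r_emotion,r_personality Target Pearson correlations between the
#'   condition label and each of the 6 emotion / 4 personality labels.
#' @param vocab_size Closed vocabulary size (default 300; must be >= 200
#'   for lexicon generation).
#' @param seed Integer seed driving every random draw.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_docs = 400L, class_balance = 0.5,
                             mean_sentences = 8, mean_sentence_len = 10,
                             sd_sentence_len = 3,
                             planted_group = "morphosyntactic",
                             effect_size = 2,
                             p_case = 0.3, p_control = 0.05,
                             r_emotion = c(0.6, 0.3, 0.2, 0.1, 0, 0),
                             r_personality = c(0.3, 0.2, 0.1, 0),
                             vocab_size = 300L, seed = 1L) {
  stopifnot(n_docs >= 2L, class_balance > 0, class_balance < 1,
            effect_size >= 0, p_case >= 0, p_case <= 1,
            p_control >= 0, p_control <= 1,
            all(abs(r_emotion) <= 1), length(r_emotion) == 6L,
            all(abs(r_personality) <= 1), length(r_personality) == 4L,
            planted_group %in% c("morphosyntactic", "stylistic", "none"))
  structure(list(n_docs = as.integer(n_docs), class_balance = class_balance,
                 mean_sentences = mean_sentences,
                 mean_sentence_len = mean_sentence_len,
                 sd_sentence_len = sd_sentence_len,
                 planted_group = planted_group, effect_size = effect_size,
                 p_case = p_case, p_control = p_control,
                 r_emotion = r_emotion, r_personality = r_personality,
                 vocab_size = as.integer(vocab_size), seed = as.integer(seed)),
            class = "generator_config")
}

# run fn with a local RNG state derived from seed + offset, restoring the
# caller's RNG afterwards
.tc_with_seed <- function(seed, offset, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 1000L + offset) %% 2147483587L)
  fn()
}

#' Closed synthetic vocabulary
#'
#' Deterministic pseudo-words built from consonant-vowel syllable units, so
#' the syllable count and character length of every word are controlled
#' (1-4 syllables). The first half of the vocabulary is designated the
#' high-register-frequency half; the halves are matched on syllable counts
#' so frequency-based planting does not leak into length-based features.
#'
#' The vocabulary, the register tables and the lexicons form a fixed
#' stated world: they depend only on `vocab_size` (not on the run seed), so
#' resources and planted word sets are shared across replicate corpora.
#'
#' @param cfg A `generator_config`.
#' @return data.frame with columns word, syllables, high_freq.
#' @export
generator_vocabulary <- function(cfg) {
  cons <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p", "r",
            "s", "t", "v", "w", "z")
  units <- as.vector(outer(cons, c("a", "e", "i", "o", "u"), paste0))
  # a final "e" would trigger the silent-e syllable rule; keep it off the
  # word-final unit so syllable counts stay exactly the unit count
  final_units <- as.vector(outer(cons, c("a", "i", "o", "u"), paste0))
  .tc_with_seed(910L + cfg$vocab_size, 1L, function() {
    syll <- rep(c(1L, 2L, 2L, 3L, 3L, 4L), length.out = cfg$vocab_size)
    words <- character(cfg$vocab_size)
    seen <- character(0)
    for (i in seq_len(cfg$vocab_size)) {
      repeat {
        w <- paste0(
          if (syll[i] > 1L)
            paste(sample(units, syll[i] - 1L, replace = TRUE), collapse = "")
          else "",
          sample(final_units, 1L))
        if (!(w %in% seen)) break
      }
      seen <- c(seen, w)
      words[i] <- w
    }
    # interleave halves by syllable count so both halves match on length
    ord <- order(syll, seq_along(syll))
    high <- logical(cfg$vocab_size)
    high[ord[seq(1L, cfg$vocab_size, by = 2L)]] <- TRUE
    data.frame(word = words, syllables = syll, high_freq = high,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic register n-gram tables
#'
#' Zipf-distributed unigram frequencies over the generator vocabulary
#' (high-frequency half gets the top ranks), with mild per-register
#' perturbation, plus "the <word>" bigrams. Deterministic under the config
#' seed.
#'
#' @param cfg A `generator_config`.
#' @return Register table structure (see [load_register_tables()]).
#' @export
generator_register_tables <- function(cfg) {
  vocab <- generator_vocabulary(cfg)
  .tc_with_seed(910L + cfg$vocab_size, 2L, function() {
    n <- nrow(vocab)
    base_rank <- integer(n)
    base_rank[vocab$high_freq] <- seq_len(sum(vocab$high_freq))
    base_rank[!vocab$high_freq] <- sum(vocab$high_freq) +
      seq_len(sum(!vocab$high_freq))
    out <- list()
    for (reg in register_names()) {
      jitter <- stats::runif(n, 0.9, 1.1)
      freq <- round(1e6 / base_rank * jitter)
      rank <- rank(-freq, ties.method = "first")
      names(freq) <- names(rank) <- vocab$word
      bi_words <- vocab$word[base_rank <= ceiling(n / 2)]
      bfreq <- round(freq[bi_words] / 10)
      names(bfreq) <- paste("the", bi_words)
      brank <- rank(-bfreq, ties.method = "first")
      out[[reg]] <- list(u = list(freq = freq, rank = rank),
                         b = list(freq = bfreq, rank = brank))
    }
    out
  })
}

#' Generate the seven stand-in lexicons
#'
#' For every category of the default LBF registry, assigns a disjoint (within
#' slot) word list drawn from the synthetic vocabulary; norm slots (ANEW,
#' SenticNet) get a norms table over half of the vocabulary. Byte-identical
#' across runs at a fixed seed.
#'
#' @param cfg A `generator_config`.
#' @param dir Optional output directory; when given, one TSV per slot is
#'   written (`lexicon_<slot>.tsv`).
#' @return Named list slot -> `tc_lexicon`.
#' @export
generate_lexicons <- function(cfg, dir = NULL) {
  if (cfg$vocab_size < 200L) {
    stop("vocabulary too small for lexicon generation (need >= 200 words)",
         call. = FALSE)
  }
  vocab <- generator_vocabulary(cfg)
  catalogue <- .tc_lbf_catalogue()
  .tc_with_seed(910L + cfg$vocab_size, 3L, function() {
    out <- list()
    for (slot in names(catalogue)) {
      spec <- catalogue[[slot]]
      if (spec$type == "category") {
        # cycle through a slot-specific shuffle; 2 words per category,
        # wrapping when a slot has more categories than vocab/2
        shuffled <- sample(vocab$word)
        per <- 2L
        categorical <- list()
        pos <- 0L
        for (key in spec$keys) {
          idx <- ((pos + seq_len(per) - 1L) %% length(shuffled)) + 1L
          categorical[[key]] <- shuffled[idx]
          pos <- pos + per
        }
        out[[slot]] <- .tc_new_lexicon(slot, categorical = categorical)
      } else {
        words <- sample(vocab$word, ceiling(nrow(vocab) / 2))
        norms <- list()
        for (key in spec$keys) {
          norms[[key]] <- stats::setNames(round(stats::runif(length(words),
                                                             1, 9), 3), words)
        }
        out[[slot]] <- .tc_new_lexicon(slot, norms = norms)
      }
    }
    if (!is.null(dir)) {
      for (slot in names(out)) {
        write_lexicon(out[[slot]],
                      file.path(dir, paste0("lexicon_",
                                            gsub("-", "", slot), ".tsv")))
      }
    }
    out
  })
}

# the planted lexicon-word set: the "sadness" categories of the emotion
# slots (known to the generator, recoverable by the tests)
#' Planted lexicon words of a generator configuration
#' @param cfg A `generator_config`.
#' @param lexicons Lexicons from [generate_lexicons()] (regenerated if NULL).
#' @return Character vector of planted words.
#' @export
planted_lexicon_words <- function(cfg, lexicons = NULL) {
  if (is.null(lexicons)) lexicons <- generate_lexicons(cfg)
  unique(c(lexicons[["EmoLex"]]$categorical[["sadness"]],
           lexicons[["ANEW-Emo"]]$categorical[["sadness"]],
           lexicons[["GALC"]]$categorical[["sadness"]]))
}

#' Generate a labeled synthetic corpus
#'
#' Case documents carry the planted signal: sentence lengths shifted by
#' `effect_size` standard deviations (planted_group "morphosyntactic") or
#' word draws biased toward the high-register-frequency vocabulary half
#' (planted_group "stylistic"), plus planted lexicon words emitted per
#' content-word slot at rate `p_case` vs `p_control`. Splits are assigned
#' deterministically 70/15/15.
#'
#' @param cfg A `generator_config`.
#' @return A `tc_corpus` data.frame (id, text, label, split).
#' @export
generate_corpus <- function(cfg) {
  vocab <- generator_vocabulary(cfg)
  lexicons <- generate_lexicons(cfg)
  planted <- planted_lexicon_words(cfg, lexicons)
  d <- cfg$effect_size
  .tc_with_seed(cfg$seed, 4L, function() {
    n <- cfg$n_docs
    label <- as.integer(stats::runif(n) < cfg$class_balance)
    split <- rep(c(rep("train", 14), rep("val", 3), rep("test", 3)),
                 length.out = n)
    texts <- character(n)
    p_high_case <- stats::plogis(d)
    p_high_ctrl <- stats::plogis(-d)
    for (i in seq_len(n)) {
      t_i <- max(2L, stats::rpois(1, cfg$mean_sentences))
      mu_len <- cfg$mean_sentence_len +
        if (cfg$planted_group == "morphosyntactic" && label[i] == 1L)
          d * cfg$sd_sentence_len else 0
      p_emit <- if (label[i] == 1L) cfg$p_case else cfg$p_control
      p_high <- if (cfg$planted_group == "stylistic") {
        if (label[i] == 1L) p_high_case else p_high_ctrl
      } else 0.5
      sents <- character(t_i)
      for (s in seq_len(t_i)) {
        len <- max(3L, round(stats::rnorm(1, mu_len, cfg$sd_sentence_len)))
        n_content <- len - 2L
        pool_high <- vocab$word[vocab$high_freq]
        pool_low <- vocab$word[!vocab$high_freq]
        from_high <- stats::runif(n_content) < p_high
        words <- ifelse(from_high,
                        sample(pool_high, n_content, replace = TRUE),
                        sample(pool_low, n_content, replace = TRUE))
        swap <- stats::runif(n_content) < p_emit
        if (any(swap)) {
          words[swap] <- sample(planted, sum(swap), replace = TRUE)
        }
        sents[s] <- paste0("the ", paste(words, collapse = " "), ".")
      }
      texts[i] <- paste(sents, collapse = " ")
    }
    df <- data.frame(id = sprintf("doc%05d", seq_len(n)), text = texts,
                     label = label, split = split, stringsAsFactors = FALSE)
    class(df) <- c("tc_corpus", class(df))
    df
  })
}

# Conditional probabilities of a binary auxiliary label A with marginal q,
# achieving Pearson/phi correlation r with a binary Y of marginal p.
.tc_phi_conditionals <- function(r, p, q) {
  s <- sqrt(q * (1 - q)) / sqrt(p * (1 - p))
  p1 <- q + r * s * (1 - p)
  p0 <- q - r * s * p
  list(p1 = p1, p0 = p0)
}

.tc_phi_feasible_range <- function(p, q) {
  # r values keeping both conditionals in [0,1]
  s <- sqrt(q * (1 - q)) / sqrt(p * (1 - p))
  lo <- max(-q / (s * (1 - p)), (q - 1) / (s * p))
  hi <- min((1 - q) / (s * (1 - p)), q / (s * p))
  c(lo, hi)
}

#' Generate auxiliary emotion and personality labels
#'
#' Binary labels drawn so that the Pearson (phi) correlation with the
#' condition label matches the configured targets, via the 2x2 contingency
#' construction: P(A=1|Y=y) chosen analytically from the target phi and the
#' marginals.
#'
#' @param cfg A `generator_config`.
#' @param corpus A corpus from [generate_corpus()].
#' @param q_emotion,q_personality Marginal P(A=1) for the auxiliary labels
#'   (defaults 0.4 and 0.5).
#' @return The corpus with `emotion` (n x 6) and `personality` (n x 4)
#'   binary matrix columns attached.
#' @export
generate_auxiliary <- function(cfg, corpus, q_emotion = 0.4,
                               q_personality = 0.5) {
  y <- corpus$label
  p <- mean(y)
  draw <- function(r_targets, q, offset) {
    .tc_with_seed(cfg$seed, offset, function() {
      sapply(seq_along(r_targets), function(j) {
        r <- r_targets[j]
        qq <- if (abs(r) >= 0.999) p else q  # degenerate construction
        cond <- .tc_phi_conditionals(r, p, qq)
        if (cond$p1 < -1e-9 || cond$p1 > 1 + 1e-9 ||
            cond$p0 < -1e-9 || cond$p0 > 1 + 1e-9) {
          rng <- .tc_phi_feasible_range(p, qq)
          stop(sprintf(paste0("target correlation %.2f infeasible for ",
                              "marginals p=%.2f q=%.2f; feasible range ",
                              "[%.2f, %.2f]"), r, p, qq, rng[1], rng[2]),
               call. = FALSE)
        }
        pr <- ifelse(y == 1L, min(max(cond$p1, 0), 1), min(max(cond$p0, 0), 1))
        as.integer(stats::runif(length(y)) < pr)
      })
    })
  }
  corpus$emotion <- draw(cfg$r_emotion, q_emotion, 5L)
  corpus$personality <- draw(cfg$r_personality, q_personality, 6L)
  corpus
}

#' Default feature-extraction resources
#'
#' Register n-gram tables and familiar-word list used when the caller does
#' not supply their own: the fixed synthetic register tables of the default
#' vocabulary size plus [default_easy_words()]. Because the generator world
#' depends only on vocabulary size, these resources match every corpus
#' generated at the default `vocab_size`, regardless of seed.
#'
#' @param cfg A `generator_config` fixing the vocabulary size.
#' @return List with `register_tables` and `easy_words`.
#' @export
default_resources <- function(cfg = generator_config()) {
  list(register_tables = generator_register_tables(cfg),
       easy_words = default_easy_words())
}

#' Write the deterministic fixture suite
#'
#' Emits the small corpus, lexicon and register-table files the test suite
#' and CLI demos consume.
#'
#' @param dir Output directory.
#' @param cfg A `generator_config` (default: 24 docs, seed 7).
#' @export
write_fixtures <- function(dir, cfg = generator_config(n_docs = 24L, seed = 7L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_auxiliary(cfg, generate_corpus(cfg))
  write_corpus_jsonl(corpus, file.path(dir, "corpus.jsonl"))
  generate_lexicons(cfg, dir = dir)
  write_register_tables(generator_register_tables(cfg),
                        file.path(dir, "register_tables.tsv"))
  invisible(dir)
}
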