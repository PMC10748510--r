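test_that("the generator world is deterministic under seed", {
  cfg <- generator_config(n_docs = 30L, seed = 77L)
  expect_identical(generate_corpus(cfg), generate_corpus(cfg))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_lexicons(cfg, dir = d1)
  generate_lexicons(cfg, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_length(f1, 7L)  # seven lexicon files
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generated lexicons cover every registry category non-emptily", {
  lex <- fx_lexicons()
  reg <- fx_registry()
  for (k in seq_len(nrow(reg$lbf))) {
    slot <- reg$lbf$group[k]; key <- reg$lbf$key[k]
    if (reg$lbf$type[k] == "category") {
      expect_gt(length(lex[[slot]]$categorical[[key]]), 0L)
    } else {
      expect_gt(length(lex[[slot]]$norms[[key]]), 0L)
    }
  }
  expect_error(generate_lexicons(generator_config(vocab_size = 150L)),
               "vocabulary too small")
})

test_that("planted lexicon-word emission rates match their targets", {
  cfg <- generator_config(n_docs = 1000L, seed = 31L, p_case = 0.3,
                          p_control = 0.05, mean_sentences = 6)
  corpus <- generate_corpus(cfg)
  planted <- planted_lexicon_words(cfg)
  rate <- function(texts) {
    toks <- unlist(strsplit(gsub("[.]", "", texts), " +"))
    toks <- toks[toks != "the" & nzchar(toks)]
    mean(toks %in% planted)
  }
  expect_lt(abs(rate(corpus$text[corpus$label == 1L]) - 0.3), 0.03)
  expect_lt(abs(rate(corpus$text[corpus$label == 0L]) - 0.05), 0.03)
  expect_lt(abs(mean(corpus$label) - 0.5), 0.05)
})

test_that("a null generator produces no detectable contour shift", {
  # scaled-down null calibration: with d = 0 and equal emission rates the
  # per-document mean sentence length must not separate the classes
  runs <- 20L
  nonsig <- 0L
  for (s in seq_len(runs)) {
    cfg <- generator_config(n_docs = 60L, seed = 4000L + s, effect_size = 0,
                            p_case = 0.05, p_control = 0.05)
    corpus <- generate_corpus(cfg)
    msl <- vapply(corpus$text, function(tx) {
      sents <- strsplit(tx, "[.] ?")[[1]]
      mean(vapply(strsplit(sents, " +"), length, integer(1)))
    }, numeric(1))
    pv <- suppressWarnings(
      stats::ks.test(msl[corpus$label == 1L], msl[corpus$label == 0L]))$p.value
    nonsig <- nonsig + (pv > 0.01)
  }
  expect_gte(nonsig, runs - 2L)
})

test_that("auxiliary labels hit their correlation targets", {
  cfg <- generator_config(n_docs = 2000L, seed = 55L,
                          r_emotion = c(0.6, 0, 0, 0, 0, 0))
  corpus <- generate_corpus(cfg)
  aux <- generate_auxiliary(cfg, corpus)
  expect_identical(dim(aux$emotion), c(2000L, 6L))
  expect_identical(dim(aux$personality), c(2000L, 4L))
  r <- label_correlations(aux$label, aux$emotion)$r
  expect_lt(abs(r[1] - 0.6), 0.06)
  expect_lt(abs(r[2]), 0.05)
  # degenerate construction: r = 1 with matched marginals clones the label
  cfg1 <- generator_config(n_docs = 500L, seed = 56L,
                           r_emotion = c(1, 0, 0, 0, 0, 0))
  aux1 <- generate_auxiliary(cfg1, generate_corpus(cfg1))
  expect_identical(aux1$emotion[, 1], aux1$label)
  # infeasible targets fail loudly with the feasible range
  cfg2 <- generator_config(n_docs = 200L, seed = 57L,
                           r_emotion = c(0.9, 0, 0, 0, 0, 0))
  expect_error(generate_auxiliary(cfg2, generate_corpus(cfg2),
                                  q_emotion = 0.05), "feasible range")
})

test_that("generated corpora round-trip through the JSONL reader", {
  cfg <- generator_config(n_docs = 15L, seed = 91L)
  corpus <- generate_auxiliary(cfg, generate_corpus(cfg))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  rt <- read_corpus_jsonl(path)
  expect_identical(rt$id, corpus$id)
  expect_identical(rt$text, corpus$text)
  expect_identical(rt$label, corpus$label)
  expect_identical(rt$split, corpus$split)
  expect_identical(unname(rt$emotion), unname(corpus$emotion))
  expect_identical(unname(rt$personality), unname(corpus$personality))
})

test_that("register tables round-trip through their TSV format", {
  tabs <- generator_register_tables(generator_config(vocab_size = 200L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_register_tables(tabs, path)
  rt <- load_register_tables(path)
  expect_setequal(names(rt), names(tabs))
  reg <- names(tabs)[1]
  expect_equal(sort(rt[[reg]]$u$freq), sort(tabs[[reg]]$u$freq))
  expect_equal(rt[[reg]]$b$freq[names(tabs[[reg]]$b$freq)],
               tabs[[reg]]$b$freq)
})
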