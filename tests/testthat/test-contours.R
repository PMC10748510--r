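test_that("window counts follow W = max(T - w + 1, 0)", {
  reg <- fx_registry()
  lex <- fx_lexicons()
  res <- fx_resources()
  five <- paste(rep("The cat sat.", 5), collapse = " ")
  cc <- extract_contours(annotate(five), reg, lex, resources = res)
  expect_identical(cc$dense$windows, 5L)
  expect_identical(nrow(cc$dense$values), 5L)
  cc3 <- extract_contours(annotate(five), reg, lex, window_len = 3L,
                          resources = res)
  expect_identical(cc3$dense$windows, 3L)
  # empty document: empty matrix and tuple set, not an error
  cc0 <- extract_contours(annotate(""), reg, lex, resources = res)
  expect_identical(cc0$dense$windows, 0L)
  expect_identical(nrow(cc0$sparse$entries), 0L)
})

test_that("sparse tuples appear iff a lexicon feature scores non-zero", {
  reg <- fx_registry()
  lex <- fx_lexicons()
  res <- fx_resources()
  # English words do not appear in the synthetic lexicons
  cc <- extract_contours(annotate("The cat sat on the mat."), reg, lex,
                         resources = res)
  expect_identical(nrow(cc$sparse$entries), 0L)
  # a planted lexicon word must produce tuples
  w <- planted_lexicon_words(fx_cfg(), lex)[1]
  cc2 <- extract_contours(annotate(paste0("The ", w, " sat.")), reg, lex,
                          resources = res)
  expect_gt(nrow(cc2$sparse$entries), 0L)
  expect_true(all(cc2$sparse$entries$score != 0))
  expect_true(all(cc2$sparse$entries$window_id >= 0L &
                    cc2$sparse$entries$window_id < cc2$sparse$windows))
  expect_false(anyDuplicated(cc2$sparse$entries[c("feature_id",
                                                  "window_id")]) > 0L)
})

test_that("densify and re-sparsify is the identity", {
  reg <- fx_registry()
  lex <- fx_lexicons()
  corpus <- fx_corpus()
  cc <- extract_contours(annotate(corpus$text[1]), reg, lex,
                         resources = fx_resources())
  m <- densify_contour(cc$sparse)
  sp2 <- sparsify_contour(m, doc_id = cc$sparse$doc_id)
  ord <- order(cc$sparse$entries$window_id, cc$sparse$entries$feature_id)
  orig <- cc$sparse$entries[ord, ]
  rownames(orig) <- NULL
  expect_equal(sp2$entries, orig)
})

test_that("context-free contour rows permute with sentence order (w=1)", {
  reg <- fx_registry()
  lex <- fx_lexicons()
  res <- fx_resources()
  corpus <- fx_corpus()
  doc <- annotate(corpus$text[2])
  perm <- rev(seq_len(doc$n_sentences))
  doc_p <- structure(list(doc_id = doc$doc_id,
                          sentences = doc$sentences[perm],
                          n_sentences = doc$n_sentences),
                     class = "annotated_text")
  a <- extract_contours(doc, reg, lex, resources = res)$dense$values
  b <- extract_contours(doc_p, reg, lex, resources = res)$dense$values
  free <- reg$glf$name[reg$glf$group != "cohesion"]  # cohesion sees context
  expect_equal(b[, free], a[perm, free])
})

test_that("adding a lexicon word never decreases its category score", {
  reg <- fx_registry()
  lex <- fx_lexicons()
  res <- fx_resources()
  w <- lex[["EmoLex"]]$categorical[["joy"]][1]
  feat <- which(reg$lbf$group == "EmoLex" & reg$lbf$key == "joy")
  score_of <- function(txt) {
    cc <- extract_contours(annotate(txt), reg, lex, resources = res)
    m <- densify_contour(cc$sparse)
    m[1, feat]
  }
  base <- sprintf("The %s came home.", w)
  more <- sprintf("The %s %s came home.", w, w)
  expect_gte(score_of(more), score_of(base))
  expect_gt(score_of(base), 0)
})

test_that("standardize_and_smooth z-scores with population SD", {
  expect_identical(standardize_and_smooth(c(2, 2, 2)), c(0, 0, 0))
  expect_equal(standardize_and_smooth(c(1, 3)), c(-1, 1))
  set.seed(1)
  for (rep in 1:5) {
    x <- rnorm(sample(3:40, 1))
    z <- standardize_and_smooth(x)
    expect_lt(abs(mean(z)), 1e-9)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  }
  x <- rnorm(25)
  expect_length(standardize_and_smooth(x, smooth = TRUE), 25L)
})

test_that("concatenated model input has width N + K = 498 and train-only scaling", {
  corpus <- fx_corpus()
  ds <- build_contour_dataset(corpus[1:20, ], fx_registry(), fx_lexicons(),
                              features = "all", resources = fx_resources())
  expect_identical(ds$input_width, 498L)
  expect_identical(sort(unname(unlist(ds$grouping))), 1:498)
  # training windows have mean ~0 per non-constant column
  tr_mat <- do.call(rbind, ds$x[ds$split == "train"])
  nonconst <- ds$scaler$sd > 0
  expect_lt(max(abs(colMeans(tr_mat)[nonconst])), 1e-9)
  expect_all_finite(tr_mat)
})

test_that("contour CSV cache round-trips", {
  cc <- extract_contours(annotate(fx_corpus()$text[3], "d3"), fx_registry(),
                         fx_lexicons(), resources = fx_resources())
  dpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_contours(cc, dpath, spath)
  rt <- read_contours(dpath, spath, doc_id = "d3")
  expect_equal(rt$dense$values, cc$dense$values, tolerance = 1e-12)
  expect_equal(rt$sparse$entries$score, cc$sparse$entries$score,
               tolerance = 1e-12)
})
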