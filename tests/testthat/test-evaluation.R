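test_that("classification metrics satisfy their definitions", {
  perfect <- classification_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(perfect[c("accuracy", "f1", "precision", "recall")]),
               c(accuracy = 100, f1 = 100, precision = 100, recall = 100))
  # positive class with TP=3, FP=1, FN=2
  gold <- c(1, 1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0)
  row <- classification_metrics(gold, pred, average = "positive")
  expect_equal(row$precision, 75)
  expect_equal(row$recall, 60)
  expect_equal(row$f1, 200 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-9)
  # all-one predictions on balanced labels: accuracy 50, flagged zero division
  bal <- classification_metrics(rep(c(1, 0), 10), rep(1, 20))
  expect_equal(bal$accuracy, 50)
  expect_true(bal$zero_division)
  expect_error(classification_metrics(c(1, 0), c(1)), "equal")
})

test_that("the F1 harmonic identity holds on every metrics row", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    gold <- rbinom(n, 1, 0.5); pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    for (avg in c("macro", "positive")) {
      row <- classification_metrics(gold, pred, average = avg)
      p <- row$precision; r <- row$recall
      f_expected <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      expect_equal(row$f1, f_expected, tolerance = 0.01)
    }
  }
})

test_that("F1 gaps reproduce the published comparison", {
  perf <- reference_table("performance")
  expect_equal(f1_gap(perf, "Stress"), -10.84, tolerance = 1e-9)
  expect_equal(f1_gap(perf, "Anxiety"), -5.69, tolerance = 1e-9)
  expect_equal(f1_gap(perf, "ADHD"), -6.15, tolerance = 1e-9)
  same <- data.frame(model = c("a", "b"), type = c("interpretable", "reference"),
                     condition = "x", f1 = c(70, 70))
  expect_equal(f1_gap(same, "x"), 0)
  expect_error(f1_gap(same, "missing"), "reference row")
  # antisymmetry under operand swap
  sw <- same; sw$type <- rev(sw$type); sw$f1 <- c(72, 70)
  expect_equal(f1_gap(same[c(1, 2), ], "x"),
               -f1_gap(data.frame(model = c("a", "b"),
                                  type = c("reference", "interpretable"),
                                  condition = "x", f1 = c(70, 70)), "x"))
})

test_that("infusion gains reproduce the published deltas", {
  fus <- reference_table("fusion")
  base <- reference_table("performance")
  base <- base[base$type == "reference", ]
  expect_equal(infusion_gain(fus, base, "ADHD", "Emotion-Infused"), 3.74,
               tolerance = 1e-9)
  expect_equal(infusion_gain(fus, base, "Anxiety", "Personality-Infused"),
               1.90, tolerance = 1e-9)
  eq <- data.frame(model = "v", condition = "c", accuracy = 70)
  expect_equal(infusion_gain(eq, data.frame(condition = "c", accuracy = 70),
                             "c", "v"), 0)
  expect_error(infusion_gain(fus, base, "ADHD", "nope"), "missing")
})

test_that("total importance sums rows and is permutation invariant", {
  glf <- reference_table("glf_importance")
  sty <- as.numeric(glf[glf$group == "Stylistic", -1])
  expect_equal(total_importance(sty), 115.07)
  lbf <- reference_table("lbf_importance")
  anew <- as.numeric(lbf[lbf$group == "ANEW", -1])
  expect_equal(total_importance(anew), 95.34)
  expect_equal(total_importance(rep(0, 5)), 0)
  set.seed(2)
  v <- runif(5, 0, 40)
  expect_identical(total_importance(v), total_importance(sample(v)))
  expect_error(total_importance(c(1, 2)), "exactly 5")
})

test_that("markdown rendering and the CLI report paths work", {
  df <- data.frame(group = c("a", "b"), score = c(1.234, 5.678))
  md <- render_markdown_table(df)
  expect_length(md, 4L)
  expect_match(md[3], "1.23", fixed = TRUE)
  out <- utils::capture.output(res <- run_cli("report"))
  expect_match(paste(out, collapse = "\n"), "115.07", fixed = TRUE)
  out2 <- utils::capture.output(res2 <- run_cli("evaluate"))
  expect_match(paste(out2, collapse = "\n"), "-10.84", fixed = TRUE)
})

test_that("the CLI simulate subcommand writes a loadable bundle", {
  dir <- withr::local_tempdir()
  suppressMessages(run_cli(c("simulate", "--n-docs", "10", "--seed", "3",
                             "--out", dir)))
  expect_true(file.exists(file.path(dir, "corpus.jsonl")))
  expect_length(list.files(dir, pattern = "^lexicon_"), 7L)
  corpus <- read_corpus_jsonl(file.path(dir, "corpus.jsonl"))
  expect_identical(nrow(corpus), 10L)
})
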