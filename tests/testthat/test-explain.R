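test_that("LIME validates inputs and is seed-deterministic", {
  oracle <- fx_linear_oracle(c(sad = 2))
  doc <- "today i feel sad and heavy but the morning helps"
  expect_error(lime_explain(oracle, doc, n_samples = 5L), ">= 10")
  r1 <- lime_explain(oracle, doc, n_samples = 100L, seed = 4L)
  r2 <- lime_explain(oracle, doc, n_samples = 100L, seed = 4L)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), length(unique(tolower(tokenize_words(doc)))))
})

test_that("LIME recovers a linear bag-of-words oracle", {
  oracle <- fx_linear_oracle(c(sad = 2, calm = -1.5))
  doc <- "today i feel sad and heavy but the calm morning helps a bit"
  hits <- 0L
  for (sd in 1:5) {
    rec <- lime_explain(oracle, doc, n_samples = 300L, seed = sd)
    ok <- rec$token[1] == "sad" &&
      rec$importance[rec$token == "sad"] > 0 &&
      rec$importance[rec$token == "calm"] < 0
    hits <- hits + ok
  }
  expect_gte(hits, 4L)
  # constant model: no attribution
  rec0 <- lime_explain(function(t) rep(0.5, length(t)), doc,
                       n_samples = 200L, seed = 1L)
  expect_lt(max(abs(rec0$importance)), 1e-3)
})

test_that("SP-LIME group importance normalizes, validates and recovers a planted group", {
  set.seed(11)
  xs <- lapply(1:12, function(i) matrix(rnorm(4 * 20), 4, 20))
  grouping <- list(g1 = 1:5, g2 = 6:12, g3 = 13:20)
  # model that only reads group g2
  planted <- function(xl) {
    vapply(xl, function(m) stats::plogis(3 * mean(m[, 6:12])), numeric(1))
  }
  hits <- 0L
  for (sd in 1:5) {
    gi <- sp_lime_group_importance(planted, xs, grouping, budget = 6L,
                                   n_samples = 120L, seed = sd * 17L)
    expect_equal(sum(gi$importance), 100, tolerance = 0.01)
    expect_setequal(gi$rank, 1:3)
    hits <- hits + (gi$group[gi$rank == 1L] == "g2" &&
                      gi$importance[gi$group == "g2"] > 50)
  }
  expect_gte(hits, 4L)
  # single group: 100 by construction
  gi1 <- sp_lime_group_importance(planted, xs, list(all = 1:20),
                                  budget = 3L, n_samples = 60L, seed = 1L)
  expect_equal(gi1$importance, 100, tolerance = 1e-9)
  # grouping must partition
  expect_error(sp_lime_group_importance(planted, xs, list(g = 1:19),
                                        seed = 1L), "partition")
})

test_that("AGRAD matches the finite-difference oracle on fixture models", {
  models <- list(fx_encoder())
  cfg2 <- generator_config(n_docs = 40L, seed = 6L)
  corpus2 <- generate_corpus(cfg2)
  models[[2]] <- train_encoder(corpus2$text, corpus2$label, corpus2$split,
                               encoder_config(n_layers = 2L, n_heads = 4L,
                                              model_dim = 16L,
                                              max_tokens = 64L, seed = 8L),
                               train_config(epochs = 1L,
                                            learning_rate = 1e-2, seed = 8L))
  docs <- list(fx_encoder_corpus()$text[1], corpus2$text[2])
  eps <- 1e-5
  for (k in 1:2) {
    m <- models[[k]]
    ag <- textcontours:::.tc_agrad_raw(m, docs[[k]], target = 1L)
    set.seed(100 + k)
    dims <- dim(ag$alpha)
    for (rep in 1:6) {
      h <- sample(dims[1], 1); q <- sample(dims[2], 1); i <- sample(dims[3], 1)
      ap <- ag$alpha; ap[h, q, i] <- ap[h, q, i] + eps
      am <- ag$alpha; am[h, q, i] <- am[h, q, i] - eps
      fd <- (textcontours:::.tc_loss_with_alpha(m, docs[[k]], 1L, ag$layer, ap) -
               textcontours:::.tc_loss_with_alpha(m, docs[[k]], 1L, ag$layer, am)) /
        (2 * eps)
      a_fd <- -fd * ag$alpha[h, q, i]
      a_an <- -ag$dalpha[h, q, i] * ag$alpha[h, q, i]
      denom <- max(abs(a_fd), 1e-10)
      expect_lt(abs(a_fd - a_an) / denom, 1e-4)
    }
    # attribution record aggregates -(dL/dalpha)*alpha over heads/queries
    rec <- agrad_attribution(m, docs[[k]], target = 1L)
    expect_identical(nrow(rec), length(ag$tokens))
    expect_equal(rec$importance,
                 apply(-ag$dalpha * ag$alpha, 3L, sum), tolerance = 1e-12)
  }
})

test_that("AGRAD refuses models without attention access", {
  fake <- structure(list(kind = "bilstm"), class = "tc_model")
  expect_error(agrad_attribution(fake, "text"), "attention")
})

test_that("top-k unigram selection follows the contract", {
  mk <- function(doc_id, n) {
    set.seed(nchar(doc_id) + n)
    data.frame(doc_id = doc_id, position = seq_len(n),
               token = paste0("w", seq_len(n)),
               importance = round(rnorm(n), 3), method = "LIME")
  }
  rec <- rbind(mk("a", 25L), mk("b", 4L))
  top <- top_k_unigrams(rec, k = 10L)
  ta <- top[top$doc_id == "a", ]
  expect_identical(nrow(ta), 10L)
  expect_true(all(diff(ta$importance) <= 0))
  expect_identical(nrow(top[top$doc_id == "b", ]), 4L)
  # ties broken by earlier position
  tie <- data.frame(doc_id = "t", position = 1:3, token = c("x", "y", "z"),
                    importance = c(1, 1, 2), method = "LIME")
  tt <- top_k_unigrams(tie, k = 2L)
  expect_identical(tt$token, c("z", "x"))
  # 30 documents with >= 10 unigrams each yield 10 * 30 records
  many <- do.call(rbind, lapply(sprintf("d%02d", 1:30), mk, n = 15L))
  expect_identical(nrow(top_k_unigrams(many, 10L)), 300L)
})

test_that("category coverage computes percentages with edge cases", {
  lex <- textcontours:::.tc_new_lexicon(
    "LIWC", categorical = list(cogproc = c("think", "know", "because"),
                               social = c("friend", "we talk")))
  topk <- data.frame(doc_id = "d", position = 1:40,
                     token = c(rep("think", 6), rep("tree", 34)),
                     importance = 1, method = "AGRAD")
  cov <- category_coverage(topk, lex, c("cogproc", "social"))
  expect_equal(cov$percentage[cov$category == "cogproc"], 15)
  expect_equal(cov$percentage[cov$category == "social"], 0)
  allin <- topk; allin$token <- "know"
  cov2 <- category_coverage(allin, lex, "cogproc")
  expect_equal(cov2$percentage, 100)
  empty <- topk[0, ]
  expect_warning(cov3 <- category_coverage(empty, lex, "cogproc"), "empty")
  expect_equal(cov3$percentage, 0)
  expect_error(category_coverage(topk, lex, "nosuch"), "not in lexicon")
})

test_that("label correlations follow the Pearson/0.00 conventions", {
  expect_equal(label_correlations(c(1, 1, 0, 0), c(1, 1, 0, 0))$r, 1)
  expect_equal(label_correlations(c(1, 1, 0, 0), c(1, 0, 1, 0))$r, 0)
  cc <- label_correlations(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(cc$r, 0)
  expect_true(cc$constant)
  expect_error(label_correlations(c(1, 0), c(1, 0, 1)), "lengths differ")
  m <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0))
  out <- label_correlations(c(1, 0, 1, 0), m)
  expect_identical(out$label, c("a", "b"))
  expect_equal(out$r, c(1, 0))
})
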