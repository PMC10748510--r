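test_that("parameter count matches the closed-form formula", {
  cfg <- bilstm_config(n_layers = 3L, hidden_dim = 512L, head_dim = 64L,
                       input_width = 498L, seed = 1L)
  # independent hand count: layer 1 both directions 4(498*512 + 512^2 + 512),
  # layers 2-3 input 1024, plus the FF head
  by_hand <- 2 * 4 * (498 * 512 + 512^2 + 512) +
    2 * (2 * 4 * (1024 * 512 + 512^2 + 512)) +
    (1024 * 64 + 64) + (64 * 64 + 64) + (64 + 1)
  expect_identical(bilstm_param_count(cfg), by_hand)

  small <- bilstm_config(n_layers = 2L, hidden_dim = 3L, head_dim = 4L,
                         input_width = 5L, seed = 1L)
  params <- textcontours:::.tc_bilstm_init(small)
  numel <- sum(vapply(rapply(params, length, how = "unlist"), identity,
                      numeric(1)))
  expect_identical(as.numeric(bilstm_param_count(small)), numel)
})

test_that("training validates widths and splits", {
  xs <- lapply(1:10, function(i) matrix(0, 3, 4))
  y <- rep(0:1, 5)
  cfg <- bilstm_config(1L, 4L, 4L, input_width = 5L)
  expect_error(train_bilstm(xs, y, rep("train", 10), cfg), "width mismatch")
  cfg2 <- bilstm_config(1L, 4L, 4L, input_width = 4L)
  expect_error(train_bilstm(xs, y, rep("train", 10), cfg2), "empty train")
})

test_that("analytic LSTM gradients agree with finite differences", {
  set.seed(42)
  xs <- lapply(1:6, function(i) matrix(rnorm(4 * 3), 4, 3))
  xs[[2]] <- xs[[2]][1:2, , drop = FALSE]  # ragged lengths exercise masking
  y <- c(0, 1, 1, 0, 1, 0)
  cfg <- bilstm_config(n_layers = 2L, hidden_dim = 3L, head_dim = 4L,
                       input_width = 3L, seed = 9L)
  params <- textcontours:::.tc_bilstm_init(cfg)
  pb <- textcontours:::.tc_pad_batch(xs)
  loss_fn <- function(p) textcontours:::.tc_bilstm_grads(p, pb$A, pb$M, y, 3L)$loss
  gr <- textcontours:::.tc_bilstm_grads(params, pb$A, pb$M, y, 3L)$grads
  eps <- 1e-6
  check <- function(path_get, path_set, g, idx) {
    p1 <- params; p2 <- params
    p1 <- path_set(p1, path_get(p1)[idx] + eps, idx)
    p2 <- path_set(p2, path_get(p2)[idx] - eps, idx)
    fd <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-4)
  }
  # spot-check entries across layers, directions and the head
  check(function(p) p$layers[[1]]$fw$W,
        function(p, v, i) {p$layers[[1]]$fw$W[i] <- v; p},
        gr$layers[[1]]$fw$W, 7L)
  check(function(p) p$layers[[2]]$bw$U,
        function(p, v, i) {p$layers[[2]]$bw$U[i] <- v; p},
        gr$layers[[2]]$bw$U, 5L)
  check(function(p) p$layers[[1]]$bw$b,
        function(p, v, i) {p$layers[[1]]$bw$b[i] <- v; p},
        gr$layers[[1]]$bw$b, 2L)
  check(function(p) p$head$W1,
        function(p, v, i) {p$head$W1[i] <- v; p},
        gr$head$W1, 3L)
})

test_that("seeded training is reproducible and learns a planted signal", {
  cfg <- generator_config(n_docs = 150L, seed = 13L)
  corpus <- generate_corpus(cfg)
  ds <- build_contour_dataset(corpus, fx_registry(), generate_lexicons(cfg),
                              features = "all",
                              resources = default_resources(cfg))
  bcfg <- bilstm_config(n_layers = 1L, hidden_dim = 16L, head_dim = 16L,
                        input_width = ds$input_width, seed = 2L)
  tcfg <- train_config(epochs = 8L, learning_rate = 3e-3, seed = 2L)
  m1 <- train_bilstm(ds$x, ds$y, ds$split, bcfg, tcfg)
  m2 <- train_bilstm(ds$x, ds$y, ds$split, bcfg, tcfg)
  expect_identical(m1$history, m2$history)  # bit-level run-to-run agreement
  expect_gte(m1$val_accuracy, 0.9)  # scaled-down planted-signal recovery
  # deterministic prediction from a fixed checkpoint
  p1 <- predict_proba(m1, ds$x[1:5])
  p2 <- predict_proba(m1, ds$x[1:5])
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("checkpoints round-trip and keep predictions identical", {
  set.seed(5)
  xs <- lapply(1:24, function(i) matrix(rnorm(3 * 4), 3, 4))
  y <- rep(0:1, 12)
  split <- rep(c("train", "val"), c(18, 6))
  m <- train_bilstm(xs, y, split,
                    bilstm_config(1L, 4L, 4L, input_width = 4L, seed = 6L),
                    train_config(epochs = 1L, seed = 6L))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(predict_proba(m2, xs[1:4]), predict_proba(m, xs[1:4]))
  bad <- withr::local_tempfile()
  saveRDS(list(format = "other"), bad)
  expect_error(load_checkpoint(bad), "not a compatible checkpoint")
})
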