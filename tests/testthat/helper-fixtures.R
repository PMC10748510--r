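# Shared fixtures, built lazily once per test run. Everything is generated
# in code from seeded configurations; nothing binary ships with the
# package.

.fx <- new.env(parent = emptyenv())

fx_registry <- function() {
  if (is.null(.fx$registry)) .fx$registry <- default_registry()
  .fx$registry
}

fx_cfg <- function() {
  if (is.null(.fx$cfg)) .fx$cfg <- generator_config(n_docs = 60L, seed = 7L)
  .fx$cfg
}

fx_lexicons <- function() {
  if (is.null(.fx$lexicons)) .fx$lexicons <- generate_lexicons(fx_cfg())
  .fx$lexicons
}

fx_resources <- function() {
  if (is.null(.fx$resources)) .fx$resources <- default_resources(fx_cfg())
  .fx$resources
}

fx_corpus <- function() {
  if (is.null(.fx$corpus)) .fx$corpus <- generate_corpus(fx_cfg())
  .fx$corpus
}

# a tiny trained encoder for explanation tests (planted lexicon signal)
fx_encoder <- function() {
  if (is.null(.fx$encoder)) {
    cfg <- generator_config(n_docs = 80L, seed = 5L)
    corpus <- generate_corpus(cfg)
    .fx$encoder_corpus <- corpus
    .fx$encoder <- train_encoder(
      corpus$text, corpus$label, corpus$split,
      encoder_config(n_layers = 2L, n_heads = 2L, model_dim = 16L,
                     max_tokens = 128L, seed = 1L),
      train_config(epochs = 4L, learning_rate = 1e-2, seed = 1L))
  }
  .fx$encoder
}

fx_encoder_corpus <- function() {
  fx_encoder()
  .fx$encoder_corpus
}

# linear bag-of-unigrams oracle (a model LIME should explain exactly)
fx_linear_oracle <- function(weights, bias = -0.2) {
  function(texts) {
    vapply(texts, function(tx) {
      tk <- tolower(tokenize_words(tx))
      s <- bias
      for (w in names(weights)) s <- s + weights[[w]] * sum(tk == w)
      stats::plogis(s)
    }, numeric(1))
  }
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(unlist(x))))
}
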