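# Multi-task fusion: a shared encoder with one primary (condition) head and
# auxiliary emotion / personality heads, trained on a weighted sum of the
# primary loss and the mean secondary loss. Auxiliary labels are typically
# "silver": produced by a model trained on an auxiliary-task corpus.

#' Fusion loss
#'
#' Weighted combination of the primary mental-health-condition loss and
#' the secondary-task loss: `lambda * l_mhc + (1 - lambda) * l_sec`.
#'
#' @param l_mhc Primary-task loss (>= 0).
#' @param l_sec Secondary-task loss (>= 0).
#' @param lambda_mhc Weight in [0, 1].
#' @return The combined loss.
#' @export
fusion_loss <- function(l_mhc, l_sec, lambda_mhc) {
  if (!is.finite(l_mhc) || !is.finite(l_sec)) {
    stop("losses must be finite", call. = FALSE)
  }
  if (!is.numeric(lambda_mhc) || lambda_mhc < 0 || lambda_mhc > 1) {
    stop("lambda_mhc must lie in [0, 1]", call. = FALSE)
  }
  lambda_mhc * l_mhc + (1 - lambda_mhc) * l_sec
}

#' Fusion configuration
#'
#' @param lambda_mhc Primary-task weight in [0, 1] (default 0.5).
#' @param secondary_tasks Non-empty subset of c("emotion", "personality").
#' @return A `fusion_config`.
#' @export
fusion_config <- function(lambda_mhc = 0.5,
                          secondary_tasks = c("emotion", "personality")) {
  secondary_tasks <- match.arg(secondary_tasks, several.ok = TRUE)
  if (!length(secondary_tasks)) {
    stop("at least one secondary task is required when fusion is enabled",
         call. = FALSE)
  }
  if (lambda_mhc < 0 || lambda_mhc > 1) {
    stop("lambda_mhc must lie in [0, 1]", call. = FALSE)
  }
  structure(list(lambda_mhc = lambda_mhc, secondary_tasks = secondary_tasks),
            class = "fusion_config")
}

#' Attach silver auxiliary labels to a corpus
#'
#' Runs a trained auxiliary model over the primary corpus and thresholds
#' the predicted probabilities at 0.5 (a probability of exactly 0.5 maps
#' to label 1). Gold condition labels are untouched.
#'
#' @param aux_model A `tc_model` trained with task "emotion" or
#'   "personality".
#' @param corpus A `tc_corpus`.
#' @return The corpus with an `emotion` (n x 6) or `personality` (n x 4)
#'   binary matrix attached.
#' @export
silver_label <- function(aux_model, corpus) {
  stopifnot(inherits(aux_model, "tc_model"))
  if (!aux_model$task %in% c("emotion", "personality")) {
    stop("aux_model must be an 'emotion' or 'personality' model, got '",
         aux_model$task, "'", call. = FALSE)
  }
  p <- predict_proba(aux_model, corpus$text, task = aux_model$task)
  if (!is.matrix(p)) p <- matrix(p, ncol = 1L)
  lab <- matrix(as.integer(p >= 0.5), nrow = nrow(p))
  corpus[[aux_model$task]] <- lab
  corpus
}

#' Train a multi-task fusion model
#'
#' Shared attention encoder with a primary head plus one head per
#' configured secondary task. The per-batch objective is
#' [fusion_loss()] of the mean primary loss and the mean secondary loss;
#' with both secondary tasks active their losses are averaged with equal
#' weight. Model selection is by primary validation accuracy.
#'
#' @param corpus A `tc_corpus` carrying gold labels plus silver labels for
#'   every configured secondary task.
#' @param fcfg A `fusion_config`.
#' @param cfg An `encoder_config`.
#' @param tcfg A `train_config`.
#' @return A `tc_model` of kind "fusion"; `$history` carries the per-epoch
#'   primary/secondary/total loss decomposition.
#' @export
train_fusion <- function(corpus, fcfg = fusion_config(),
                         cfg = encoder_config(),
                         tcfg = train_config(learning_rate = 1e-3)) {
  for (task in fcfg$secondary_tasks) {
    if (is.null(corpus[[task]])) {
      stop("missing silver labels for secondary task '", task, "'",
           call. = FALSE)
    }
  }
  lambda <- fcfg$lambda_mhc
  n_sec <- length(fcfg$secondary_tasks)
  texts <- corpus$text
  split <- corpus$split
  tr <- which(split == "train"); va <- which(split == "val")
  if (!length(tr) || !length(va)) stop("empty train or validation split",
                                       call. = FALSE)
  vocab <- build_vocab(texts[tr], cfg)
  params <- .tc_encoder_init(cfg, length(vocab),
                             tasks = c("primary", fcfg$secondary_tasks))
  state <- .tc_adam_init(params)
  enc <- lapply(texts, .tc_encode_ids, vocab = vocab,
                max_tokens = cfg$max_tokens)
  weights <- list(primary = lambda)
  for (task in fcfg$secondary_tasks) weights[[task]] <- (1 - lambda) / n_sec
  best <- list(acc = -1, params = params)
  history <- list()
  .tc_with_seed(tcfg$seed, 51L, function() {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(tr)
      sums <- c(primary = 0, secondary = 0, total = 0); nb <- 0L
      for (s in seq(1L, length(ord), by = tcfg$batch_size)) {
        idx <- ord[s:min(s + tcfg$batch_size - 1L, length(ord))]
        grads <- .tc_zero_like(params)
        bp <- 0; bs <- 0
        for (b in idx) {
          fwd <- .tc_encoder_forward_doc(params, cfg, enc[[b]]$ids)
          tg <- list(primary = corpus$label[b])
          for (task in fcfg$secondary_tasks) tg[[task]] <- corpus[[task]][b, ]
          hl <- .tc_head_loss_doc(params, fwd$u, tg, weights)
          bp <- bp + hl$parts$primary
          bs <- bs + mean(unlist(hl$parts[fcfg$secondary_tasks]))
          for (task in names(tg)) {
            dl <- attr(hl$parts, paste0("dlogit_", task))
            grads$heads[[task]]$W <- grads$heads[[task]]$W + outer(fwd$u, dl)
            grads$heads[[task]]$b <- grads$heads[[task]]$b + dl
          }
          grads <- .tc_encoder_backward_doc(params, cfg, enc[[b]]$ids, fwd,
                                            hl$du, grads)$grads
        }
        grads <- rapply(grads, function(g) g / length(idx), how = "replace")
        stp <- .tc_adam_step(params, grads, state, tcfg$learning_rate,
                             tcfg$weight_decay)
        params <<- stp$params; state <<- stp$state
        lp <- bp / length(idx); ls <- bs / length(idx)
        sums <- sums + c(lp, ls, fusion_loss(lp, ls, lambda))
        nb <- nb + 1L
      }
      hd <- params$heads$primary
      pv <- vapply(va, function(b) {
        fwd <- .tc_encoder_forward_doc(params, cfg, enc[[b]]$ids)
        as.numeric(.tc_sigmoid(fwd$u %*% hd$W + hd$b))
      }, numeric(1))
      acc <- mean((pv >= 0.5) == corpus$label[va])
      history[[ep]] <<- data.frame(
        epoch = ep, split = "val",
        loss_primary = sums[[1]] / nb, loss_secondary = sums[[2]] / nb,
        loss_total = sums[[3]] / nb, accuracy = acc)
      if (acc > best$acc) best <<- list(acc = acc, params = params)
    }
  })
  structure(list(kind = "fusion", cfg = cfg, tcfg = tcfg, fcfg = fcfg,
                 task = "primary", vocab = vocab, params = best$params,
                 val_accuracy = best$acc,
                 history = do.call(rbind, history)),
            class = "tc_model")
}
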