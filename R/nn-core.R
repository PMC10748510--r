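# Minimal neural-network utilities shared by the BiLSTM and the attention
# encoder: seeded initialisation, Adam on nested parameter lists, and
# binary cross-entropy. Implemented in base R matrix code; no deep-learning
# framework is available offline, and the explanation stack needs direct
# access to intermediate gradients anyway.

.tc_sigmoid <- function(x) 1 / (1 + exp(-x))

.tc_glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# elementwise binary cross-entropy; p clipped for numerical safety
.tc_bce <- function(p, y, eps = 1e-9) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# nested-list Adam with classic L2 weight decay
.tc_adam_init <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else x * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.tc_adam_step <- function(params, grads, state, lr, weight_decay = 0,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t_ <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t_)
    vhat <- v / (1 - beta2^t_)
    p_new <- p - lr * mhat / (sqrt(vhat) + eps)
    if (is.null(dim(p))) p_new <- as.numeric(p_new)
    list(p = p_new, m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t_))
}

# grads must mirror params structurally; build a zeroed copy
.tc_zero_like <- function(params) {
  f <- function(x) if (is.list(x)) lapply(x, f) else x * 0
  f(params)
}
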