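# Dense-network primitives ---------------------------------------------------
#
# Minimal forward/backward implementations of the layers used by the
# trainable heads: dense, batch normalisation, ReLU, inverted dropout,
# sigmoid, plus the Adam optimiser.  Backbones are frozen, so gradients
# only ever flow through these layers (and, for Grad-CAM, back to the
# flattened backbone features, where every layer is linear or piecewise
# linear in inference mode).

BN_EPS <- 1e-3
# Running-moment momentum.  0.9 rather than the common 0.99: with a few
# hundred training images there are only ~10 batches per epoch, and the
# inference statistics must converge within the early-stopping window.
BN_MOMENTUM <- 0.9

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(x, b) sweep(x, 2L, b, `+`)

# Batch normalisation, training mode.  Returns output, cache for backward,
# and updated running moments.
bn_forward_train <- function(x, gamma, beta, run_mean, run_var) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, `-`)
  v <- colMeans(xc^2)                       # population variance
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(xc, 2L, istd, `*`)
  out <- add_bias(sweep(xhat, 2L, gamma, `*`), beta)
  list(out = out,
       cache = list(xhat = xhat, istd = istd, gamma = gamma),
       run_mean = BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu,
       run_var = BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v * n /
         max(n - 1L, 1L))
}

bn_forward_infer <- function(x, gamma, beta, run_mean, run_var) {
  scale <- gamma / sqrt(run_var + BN_EPS)
  add_bias(sweep(sweep(x, 2L, run_mean, `-`), 2L, scale, `*`), beta)
}

bn_backward <- function(dout, cache) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, cache$gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)), per column
  dx <- sweep(sweep(dxhat, 2L, m1, `-`) - sweep(xhat, 2L, m2, `*`),
              2L, cache$istd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout mask (training); scaling keeps inference a no-op.
dropout_mask <- function(n, p, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(n * p) >= rate) / (1 - rate), n, p)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

# params/grads are (possibly nested) lists of numeric arrays with matching
# structure; returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}
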