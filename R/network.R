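# Minimal dense-network machinery: affine layers with optional rectifier,
# manual backprop, and an Adam optimizer. Everything is plain matrices so the
# whole model is serializable and bit-reproducible under a seed; the heavy
# lifting is BLAS matrix products.

# Fan-in-scaled uniform initialization, U(-1/sqrt(fan_in), +1/sqrt(fan_in))
# for weights and biases — the conservative scale keeps early training from
# memorizing high-dimensional noise before the validation-based stopper can
# act. Draws from the ambient RNG so callers control determinism with one
# seed.
mlp_init <- function(dims, relu) {
  n_layers <- length(dims) - 1L
  stopifnot(length(relu) == n_layers)
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    bound <- 1 / sqrt(dims[l])
    W[[l]] <- matrix(
      runif(dims[l] * dims[l + 1L], -bound, bound),
      nrow = dims[l], ncol = dims[l + 1L]
    )
    b[[l]] <- runif(dims[l + 1L], -bound, bound)
  }
  list(W = W, b = b, relu = relu, dims = dims)
}

# Forward pass; with cache = TRUE keeps pre/post-activation matrices for
# backprop. x is n x dims[1].
mlp_forward <- function(net, x, cache = FALSE) {
  h <- x
  acts <- if (cache) vector("list", length(net$W)) else NULL
  ins <- if (cache) vector("list", length(net$W)) else NULL
  for (l in seq_along(net$W)) {
    if (cache) ins[[l]] <- h
    a <- h %*% net$W[[l]]
    a <- sweep(a, 2, net$b[[l]], "+")
    if (net$relu[l]) a[a < 0] <- 0
    if (cache) acts[[l]] <- a
    h <- a
  }
  if (cache) list(out = h, ins = ins, acts = acts) else h
}

# Backprop from grad_out (gradient w.r.t. the network output) to parameter
# gradients and the gradient w.r.t. the input.
mlp_backward <- function(net, fwd, grad_out) {
  n_layers <- length(net$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  g <- grad_out
  for (l in rev(seq_len(n_layers))) {
    if (net$relu[l]) g <- g * (fwd$acts[[l]] > 0)
    gW[[l]] <- crossprod(fwd$ins[[l]], g)
    gb[[l]] <- colSums(g)
    g <- tcrossprod(g, net$W[[l]])
  }
  list(W = gW, b = gb, g_in = g)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(
    mW = zero_like(net$W), vW = zero_like(net$W),
    mb = zero_like(net$b), vb = zero_like(net$b), t = 0L
  )
}

adam_step <- function(net, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# Early-stopping bookkeeping: strict improvement resets the counter; training
# stops after `patience` consecutive epochs without improvement, and the
# parameters from the best-validation epoch are kept.
early_stopper <- function(patience) {
  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$wait <- 0L
  env$best_epoch <- 0L
  env$snapshot <- NULL
  list(
    update = function(val, epoch, params) {
      if (val < env$best) {
        env$best <- val
        env$best_epoch <- epoch
        env$snapshot <- params
        env$wait <- 0L
      } else {
        env$wait <- env$wait + 1L
      }
      env$wait >= patience
    },
    best = function() list(
      val = env$best, epoch = env$best_epoch, params = env$snapshot
    )
  )
}
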