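# Minimal fully connected network engine: dense layers, rectifier
# activations, mean-absolute-error loss, Adam. Written on base matrix
# algebra (BLAS) so training stays CPU-friendly; all randomness is seeded.

mlp_init <- function(layer_sizes, seed = 1L) {
  L <- length(layer_sizes) - 1L
  with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      # He initialization, suited to rectifier units
      W[[l]] <- matrix(
        rnorm(fan_in * layer_sizes[l + 1], 0, sqrt(2 / fan_in)),
        fan_in, layer_sizes[l + 1]
      )
      b[[l]] <- rep(0, layer_sizes[l + 1])
    }
    list(W = W, b = b, sizes = layer_sizes)
  })
}

# Forward pass; keep = TRUE retains activations for backprop.
mlp_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  acts <- if (keep) vector("list", L + 1L) else NULL
  A <- X
  if (keep) acts[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    A <- if (l < L) pmax(Z, 0) else Z # linear output layer
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

# Gradients of mean(|Y - Yhat|) (mean over all entries) w.r.t. weights.
mlp_grad <- function(net, fwd, Y) {
  L <- length(net$W)
  n_entries <- length(Y)
  delta <- sign(fwd$out - Y) / n_entries
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    A_prev <- fwd$acts[[l]]
    gW[[l]] <- crossprod(A_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, net$W[[l]])
      delta <- delta * (fwd$acts[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zeros <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  }
  list(
    mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
    mb = lapply(net$b, zeros), vb = lapply(net$b, zeros),
    t = 0L
  )
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

mlp_mae <- function(net, X, Y, chunk = 4096L) {
  n <- nrow(X)
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    pred <- mlp_forward(net, X[s:e, , drop = FALSE])
    tot <- tot + sum(abs(pred - Y[s:e, , drop = FALSE]))
  }
  tot / (n * ncol(Y))
}

# Input-gradient of one output unit at one input row (exact backprop).
mlp_input_grad <- function(net, x, output_index) {
  fwd <- mlp_forward(net, matrix(x, nrow = 1L), keep = TRUE)
  L <- length(net$W)
  delta <- matrix(0, 1L, ncol(fwd$out))
  delta[1L, output_index] <- 1
  for (l in rev(seq_len(L))) {
    delta <- tcrossprod(delta, net$W[[l]])
    if (l > 1L) delta <- delta * (fwd$acts[[l]] > 0)
  }
  drop(delta)
}
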