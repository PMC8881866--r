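# Minimal fully-connected network engine: ReLU hidden layers, a linear /
# sigmoid / softmax head, manual backprop and Adam. All three model networks
# (selector, counterfactual predictor, factual predictor) are instances.

mlp_init <- function(input_dim, hidden, output_dim, head = c("linear", "sigmoid", "softmax")) {
  head <- match.arg(head)
  sizes <- c(input_dim, hidden, output_dim)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialisation; the last layer is scaled down so heads start near
    # their neutral point (softmax ~ uniform, sigmoid ~ 0.5)
    sd <- if (l == L) 0.01 else sqrt(2 / sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sd),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, head = head, sizes = sizes), class = "cfs_mlp")
}

mlp_head <- function(Z, head) {
  switch(head,
    linear  = Z,
    sigmoid = 1 / (1 + exp(-Z)),
    softmax = {
      Z <- Z - apply(Z, 1L, max)
      E <- exp(Z)
      E / rowSums(E)
    })
}

# Forward pass. X is n x input_dim. With keep = TRUE the per-layer
# post-activations and ReLU masks needed for backprop are returned.
mlp_forward <- function(net, X, keep = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$sizes[1L])
    stop("input has ", ncol(X), " columns; network expects ", net$sizes[1L])
  L <- length(net$W)
  A <- vector("list", L + 1L)
  M <- vector("list", L)
  A[[1L]] <- X
  H <- X
  for (l in seq_len(L)) {
    Z <- sweep(H %*% net$W[[l]], 2L, net$b[[l]], "+")
    if (l < L) {
      M[[l]] <- Z > 0
      H <- Z * M[[l]]
      A[[l + 1L]] <- H
    } else {
      H <- mlp_head(Z, net$head)
      A[[l + 1L]] <- H
    }
  }
  if (keep) list(out = H, A = A, M = M) else H
}

# Backprop from dL/d(final pre-activation). Returns parameter gradients and,
# when input_grad = TRUE, dL/dX as well.
mlp_backward <- function(net, fw, dZ, input_grad = FALSE) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1L) {
      dZ <- (dZ %*% t(net$W[[l]])) * fw$M[[l - 1L]]
    } else if (input_grad) {
      dX <- dZ %*% t(net$W[[1L]])
    }
  }
  out <- list(W = gW, b = gb)
  if (input_grad) out$dX <- dX
  out
}

# Row-wise gradient of a single head output unit with respect to the inputs.
# For a softmax head this is the gradient of the post-softmax probability.
mlp_input_grad <- function(net, X, unit) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  fw <- mlp_forward(net, X, keep = TRUE)
  P <- fw$out
  k <- ncol(P)
  dZ <- switch(net$head,
    linear = {
      D <- matrix(0, nrow(P), k)
      D[, unit] <- 1
      D
    },
    sigmoid = {
      D <- matrix(0, nrow(P), k)
      D[, unit] <- P[, unit] * (1 - P[, unit])
      D
    },
    softmax = {
      # d p_unit / d z_j = p_unit (1[j = unit] - p_j)
      D <- -P * P[, unit]
      D[, unit] <- D[, unit] + P[, unit]
      D
    })
  mlp_backward(net, fw, dZ, input_grad = TRUE)$dX
}

adam_init <- function(net) {
  zeros <- function(p) lapply(p, function(x) x * 0)
  list(mW = zeros(net$W), vW = zeros(net$W),
       mb = zeros(net$b), vb = zeros(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
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
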