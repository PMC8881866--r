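# Shared brute-force oracles for the score-function gradient of the
# selection policy (exhaustive mask enumeration at small d).

all_masks <- function(d) {
  as.matrix(expand.grid(rep(list(c(0, 1)), d)))
}

# Exact policy objective for one instance:
#   l3(x) = sum_s pi(s | x) * (lhat(s) + lambda * |s|_0)
enum_policy_objective <- function(sel_net, x, lhat, lambda) {
  p <- drop(cfsace:::mlp_forward(sel_net, matrix(x, 1)))
  S <- all_masks(length(p))
  pis <- apply(S, 1, function(s) prod(p^s * (1 - p)^(1 - s)))
  vals <- apply(S, 1, lhat)
  sum(pis * (vals + lambda * rowSums(S)))
}

# Expectation (over the policy) of the implementation's per-mask surrogate
# gradient: E_s[lhat(s) * d log pi / d theta] + lambda * d (sum_i p_i) / d theta.
expected_surrogate_grad <- function(sel_net, x, lhat, lambda) {
  fw <- cfsace:::mlp_forward(sel_net, matrix(x, 1), keep = TRUE)
  p <- drop(fw$out)
  S <- all_masks(length(p))
  pis <- apply(S, 1, function(s) prod(p^s * (1 - p)^(1 - s)))
  # policy-weighted expectation of the per-mask pre-activation gradient of
  # the score term lhat(s) * log pi(s), plus the pathwise expected-sparsity
  # term lambda * p (1 - p), exactly as the training step forms it
  dZ_score <- colSums(pis * apply(S, 1, lhat) * sweep(S, 2, p))
  dZ <- matrix(dZ_score + lambda * p * (1 - p), 1)
  g <- cfsace:::mlp_backward(sel_net, fw, dZ)
  list(W = g$W, b = g$b)
}

# Finite-difference gradient of the enumerated objective in the selector
# parameters.
fd_policy_grad <- function(sel_net, x, lhat, lambda, h = 1e-6) {
  obj <- function(n) enum_policy_objective(n, x, lhat, lambda)
  g <- list(W = lapply(sel_net$W, function(w) w * 0),
            b = lapply(sel_net$b, function(b) b * 0))
  for (l in seq_along(sel_net$W)) {
    for (k in seq_along(sel_net$W[[l]])) {
      np <- sel_net; np$W[[l]][k] <- np$W[[l]][k] + h
      nm <- sel_net; nm$W[[l]][k] <- nm$W[[l]][k] - h
      g$W[[l]][k] <- (obj(np) - obj(nm)) / (2 * h)
    }
    for (k in seq_along(sel_net$b[[l]])) {
      np <- sel_net; np$b[[l]][k] <- np$b[[l]][k] + h
      nm <- sel_net; nm$b[[l]][k] <- nm$b[[l]][k] - h
      g$b[[l]][k] <- (obj(np) - obj(nm)) / (2 * h)
    }
  }
  g
}
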