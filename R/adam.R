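# Adam optimizer over a flat list of parameter matrices.
# Standard first/second-moment estimates with bias correction
# (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Glorot (Xavier) uniform initialization; draws from the current RNG
# stream so callers control determinism with set.seed().
glorot_uniform <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# Numerically stable helpers shared by both training stages.
sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
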