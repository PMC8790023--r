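# Shared fixtures and independent oracles for the test suite.

# Naive per-node message-passing oracle for the graph-convolution forward
# pass: per layer, sum A_hat[i,k] * H[k,] over k with explicit loops, then
# multiply by W and apply ReLU.
naive_gcn_forward <- function(X, A_hat, weights) {
  H <- X
  for (W in weights) {
    n <- nrow(H)
    agg <- matrix(0, n, ncol(H))
    for (i in seq_len(n))
      for (k in seq_len(n))
        agg[i, ] <- agg[i, ] + A_hat[i, k] * H[k, ]
    Z <- agg %*% W
    H <- matrix(pmax(Z, 0), nrow(Z), ncol(Z))
  }
  H
}

# Brute-force Mann-Whitney AUC: pairwise positive/negative comparisons,
# ties counted one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos)
    for (b in neg)
      total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# A small random bipartite problem with adjacency and one modal input.
random_problem <- function(p, q, d_u, seed) {
  set.seed(seed)
  B <- matrix(rbinom(p * q, 1, 0.4), p, q)
  if (sum(B) == 0) B[1, 1] <- 1
  X <- pad_and_stack(matrix(rnorm(p * d_u), p, d_u),
                     matrix(rnorm(q * d_u), q, d_u), 1L)
  list(B = B, A_hat = normalize_adjacency(build_adjacency(B)), X = X)
}

# A tiny but complete synthetic study used across tests: generated data,
# imputed features, positives.
tiny_study <- function(seed = 1L, p = 12L, q = 15L, density = 0.15) {
  sim <- generate_synthetic(synthetic_spec(p = p, q = q, latent_rank = 2L,
                                           density = density, seed = seed))
  list(sim = sim,
       features = impute_feature_set(sim$features),
       positives = ammgc:::positive_pairs(sim$dataset$B))
}

fast_config <- function(seed = 1L, epochs = 30L)
  train_config(seed = seed, h1 = 16L, d = 8L, epochs = epochs)

# Study-scale configuration used by the synthetic recovery experiments:
# embedding widths scaled to the 70-node graph.
study_config <- function(seed) train_config(seed = seed, h1 = 32L, d = 16L)

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
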