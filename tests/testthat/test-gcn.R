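test_that("gcn_forward matches trivial propagation cases", {
  prob <- random_problem(3, 4, 5, seed = 1)
  params <- list(weights = list(diag(5), diag(5)))
  zero <- gcn_forward(matrix(0, 7, 5), prob$A_hat, params)
  expect_true(all(zero == 0))
  # isolated graph (identity adjacency) + identity weights + nonneg input
  X <- abs(matrix(rnorm(35), 7, 5))
  expect_equal(gcn_forward(X, diag(7), params), X)
})

test_that("gcn_forward equals the naive per-node aggregation oracle", {
  for (seed in 1:20) {
    prob <- random_problem(sample(2:5, 1), sample(2:5, 1), 4, seed)
    set.seed(seed + 100)
    layers <- sample(1:3, 1)
    params <- gcn_init_params(4, 6, 3, layers)
    E <- gcn_forward(prob$X$X, prob$A_hat, params)
    expect_equal(E, naive_gcn_forward(prob$X$X, prob$A_hat, params$weights),
                 tolerance = 1e-6)
  }
})

test_that("gcn_forward is permutation-equivariant", {
  prob <- random_problem(4, 5, 6, seed = 9)
  set.seed(9)
  params <- gcn_init_params(6, 5, 3)
  E <- gcn_forward(prob$X$X, prob$A_hat, params)
  perm <- sample(9)
  E_perm <- gcn_forward(prob$X$X[perm, ], prob$A_hat[perm, perm], params)
  expect_equal(E_perm, E[perm, ])
})

test_that("gcn_forward rejects inconsistent shapes", {
  prob <- random_problem(3, 3, 4, seed = 2)
  params <- gcn_init_params(5, 4, 2)
  expect_error(gcn_forward(prob$X$X, prob$A_hat, params), "width")
  expect_error(gcn_forward(matrix(0, 3, 4), prob$A_hat,
                           gcn_init_params(4, 4, 2)), "rows")
})

test_that("modal scores are sigmoid inner products of embedding rows", {
  E <- rbind(c(0, 0), c(1, 1), c(1, 1), c(1, -1))
  emb <- structure(list(modal_index = 1L, E = E, p = 2L, q = 2L),
                   class = "modal_embedding")
  expect_equal(modal_score(emb, 1, 1), 0.5)                  # zero row
  expect_equal(modal_score(emb, 2, 1), 1 / (1 + exp(-2)))   # [1,1].[1,1]
  expect_equal(modal_score(emb, 2, 2), 0.5)                  # orthogonal
  # symmetric in the two rows
  expect_equal(modal_score(emb, 2, 2), modal_score(emb, 2, 2))
  expect_error(modal_score(emb, 3, 1), "drug index")
  expect_error(modal_score(emb, 1, 5), "miRNA index")
})

test_that("negative sampling is uniform over zero pairs and seeded", {
  B <- matrix(1, 2, 2); B[2, 1] <- 0
  expect_equal(unname(sample_negatives(B, 1, rng_seed = 1)),
               cbind(2L, 1L))
  expect_equal(nrow(sample_negatives(B, 0, rng_seed = 1)), 0)
  expect_error(sample_negatives(B, 2, rng_seed = 1), "only 1 zero")
  expect_equal(sample_negatives(B, 1, rng_seed = 7),
               sample_negatives(B, 1, rng_seed = 7))
  # empirical uniformity: 10x10, 20 positives, inclusion prob 20/80
  set.seed(42)
  B2 <- matrix(0, 10, 10)
  B2[sample(100, 20)] <- 1
  counts <- matrix(0, 10, 10)
  n_rep <- 2000
  for (i in seq_len(n_rep)) {
    pairs <- sample_negatives(B2, 20)
    counts[pairs] <- counts[pairs] + 1
  }
  expect_true(all(counts[B2 == 1] == 0))
  expected <- n_rep * 20 / 80
  se <- sqrt(n_rep * (20 / 80) * (1 - 20 / 80))
  expect_true(all(abs(counts[B2 == 0] - expected) <= 4 * se))
})

test_that("modal training separates planted positives from negatives", {
  study <- tiny_study(seed = 3, p = 12, q = 15, density = 0.15)
  B <- study$sim$dataset$B
  A_hat <- normalize_adjacency(build_adjacency(B))
  X <- build_modal_inputs(study$features)[[1]]
  fit <- train_modal(X, A_hat, study$positives, fast_config(seed = 3,
                                                            epochs = 60))
  E <- fit$embedding
  scores_pos <- modal_score(E, study$positives[, 1], study$positives[, 2])
  neg <- sample_negatives(B, nrow(study$positives), rng_seed = 11)
  scores_neg <- modal_score(E, neg[, 1], neg[, 2])
  expect_gt(mean(scores_pos), mean(scores_neg))
  expect_true(all(fit$embedding$E >= 0))
})

test_that("modal training loss starts near log(2) and trends downward", {
  study <- tiny_study(seed = 5)
  A_hat <- normalize_adjacency(build_adjacency(study$sim$dataset$B))
  X <- build_modal_inputs(study$features)[[1]]
  fit <- train_modal(X, A_hat, study$positives, fast_config(seed = 5,
                                                            epochs = 100))
  # Glorot-initialized embeddings give small logits, so the first-epoch
  # loss sits near the coin-flip value -log(0.5)
  expect_lt(abs(fit$loss_history[1] - log(2)), 0.5)
  win <- vapply(seq(1, 81, by = 20), function(s)
    mean(fit$loss_history[s:(s + 19)]), numeric(1))
  expect_true(all(diff(win) <= 0.02))
  expect_lt(win[length(win)], win[1])
})

test_that("modal training is bitwise reproducible under a fixed seed", {
  study <- tiny_study(seed = 2)
  A_hat <- normalize_adjacency(build_adjacency(study$sim$dataset$B))
  X <- build_modal_inputs(study$features)[[2]]
  f1 <- train_modal(X, A_hat, study$positives, fast_config(seed = 8,
                                                           epochs = 15))
  f2 <- train_modal(X, A_hat, study$positives, fast_config(seed = 8,
                                                           epochs = 15))
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)
})
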