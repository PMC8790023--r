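make_emb <- function(E, p, q, u = 1L)
  structure(list(modal_index = u, E = E, p = p, q = q),
            class = "modal_embedding")

test_that("attention vectors are the affine projection W E + b", {
  E <- rbind(c(2, 0), c(0, 3))
  expect_equal(attention_weights(E, c(0, 0), c(1, 1)),
               matrix(1, 1, 2))
  expect_equal(attention_weights(E, c(1, 1), c(0, 0)),
               matrix(c(2, 3), 1, 2))
  # square identity embedding returns W itself
  expect_equal(attention_weights(diag(3), c(4, 5, 6), rep(0, 3)),
               matrix(c(4, 5, 6), 1, 3))
  expect_error(attention_weights(E, c(1, 1, 1), c(0, 0)), "columns")
  expect_error(attention_weights(E, c(1, 1), c(0, 0, 0)), "columns")
})

test_that("fusion concatenates dimension-rescaled modal blocks", {
  p <- 1L; q <- 1L
  embs <- lapply(1:4, function(u) make_emb(matrix(c(1, 2, 1, 2), 2, 2), p, q, u))
  ones <- lapply(1:4, function(u) c(1, 1))
  Z1 <- fuse(embs, g_override = ones)
  expect_equal(Z1$Z, do.call(cbind, lapply(embs, `[[`, "E")))
  # a zeroed attention vector blanks that modal's block
  g <- ones; g[[2]] <- c(0, 0)
  Z2 <- fuse(embs, g_override = g)
  expect_true(all(Z2$Z[, 3:4] == 0))
  # column-wise scaling by hand
  one <- list(make_emb(matrix(c(1, 2), 1, 2), 1L, 0L))
  Z3 <- fuse(one, g_override = list(c(3, 4)))
  expect_equal(Z3$Z, matrix(c(3, 8), 1, 2))
  # block extraction recovers E diag(g) exactly
  set.seed(6)
  g4 <- lapply(1:4, function(u) rnorm(2))
  Z4 <- fuse(embs, g_override = g4)
  for (u in 1:4)
    expect_equal(Z4$Z[, (2 * u - 1):(2 * u)],
                 embs[[u]]$E %*% diag(g4[[u]]))
  bad <- embs
  bad[[3]] <- make_emb(matrix(1, 2, 3), p, q, 3L)
  expect_error(fuse(bad, g_override = ones), "widths")
})

test_that("final scores are sigmoid inner products of attentive rows", {
  Z <- structure(list(Z = rbind(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)),
                      p = 1L, q = 2L, d = 3L),
                 class = "attentive_embedding")
  expect_equal(final_score(Z, 1, 1), 0.5)
  Z$Z[1, ] <- c(1, 1, 1)  # identical rows with squared norm 3
  expect_equal(final_score(Z, 1, 1), 1 / (1 + exp(-3)))
  expect_error(final_score(Z, 2, 1), "drug index")
  # invariance under a simultaneous orthogonal rotation of all rows
  set.seed(8)
  Zr <- matrix(rnorm(15), 5, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  za <- structure(list(Z = Zr, p = 2L, q = 3L, d = 3L),
                  class = "attentive_embedding")
  zb <- structure(list(Z = Zr %*% Q, p = 2L, q = 3L, d = 3L),
                  class = "attentive_embedding")
  expect_equal(final_score(za, c(1, 2), c(1, 3)),
               final_score(zb, c(1, 2), c(1, 3)))
})

test_that("pos_weight is the negative:positive pair ratio", {
  expect_equal(compute_pos_weight(106, 754, 3338), 76586 / 3338)
  expect_equal(compute_pos_weight(10, 10, 50), 1)
  expect_equal(compute_pos_weight(4, 5, 20), 0)
  expect_error(compute_pos_weight(4, 5, 0), "positive")
  expect_error(compute_pos_weight(2, 2, 5), "exceeds")
})

test_that("weighted loss with pos_weight 1 equals unweighted cross-entropy", {
  # balanced labels make pos_weight exactly 1; the recorded first-epoch
  # loss must match a hand-computed unweighted BCE at the same init
  set.seed(21)
  p <- 4L; q <- 5L; d <- 3L
  embs <- lapply(1:4, function(u)
    make_emb(abs(matrix(rnorm((p + q) * d), p + q, d)) / 4, p, q, u))
  pos <- ammgc:::positive_pairs(matrix(rep(c(1, 0), 10), p, q))
  stopifnot(nrow(pos) == p * q / 2)
  cfg <- train_config(seed = 31, d = d, epochs = 1L)
  fit <- train_attention(embs, pos, NULL, cfg)
  set.seed(31)
  flat <- unlist(lapply(1:4, function(u)
    list(ammgc:::glorot_uniform(1, p + q), matrix(0, 1, d))),
    recursive = FALSE)
  S <- matrix(0, p, q)
  for (u in 1:4) {
    g <- flat[[2 * u - 1]] %*% embs[[u]]$E + flat[[2 * u]]
    S <- S + (embs[[u]]$E[1:p, ] * rep(g^2, each = p)) %*%
      t(embs[[u]]$E[p + 1:q, ])
  }
  Y <- matrix(0, p, q); Y[pos] <- 1
  plain_bce <- mean(-Y * log(ammgc:::sigmoid(S)) -
                      (1 - Y) * log(1 - ammgc:::sigmoid(S)))
  expect_equal(fit$loss_history[1], plain_bce, tolerance = 1e-10)
})

test_that("attention training is deterministic and rejects empty input", {
  study <- tiny_study(seed = 4)
  A_hat <- normalize_adjacency(build_adjacency(study$sim$dataset$B))
  inputs <- build_modal_inputs(study$features)
  embs <- lapply(1:4, function(u)
    train_modal(inputs[[u]], A_hat, study$positives,
                fast_config(seed = u, epochs = 10))$embedding)
  a1 <- train_attention(embs, study$positives, NULL,
                        train_config(seed = 5, d = 8L, epochs = 20L))
  a2 <- train_attention(embs, study$positives, NULL,
                        train_config(seed = 5, d = 8L, epochs = 20L))
  expect_identical(a1$attentive$g, a2$attentive$g)
  expect_error(train_attention(embs, study$positives[0, , drop = FALSE],
                               NULL), "no training positives")
})

test_that("attention upweights the modal whose embeddings carry signal", {
  # embeddings handed directly: modal 1 aligned with the planted factors,
  # modals 2-4 random noise of matched scale
  wins <- 0L
  for (s in 1:3) {
    set.seed(s)
    p <- 30L; q <- 40L; d <- 16L; r <- 4L
    U <- matrix(rnorm(p * r), p, r); V <- matrix(rnorm(q * r), q, r)
    logits <- 2 * tcrossprod(U, V) / sqrt(r)
    off <- ammgc:::solve_density_offset(logits, 0.05)
    B <- matrix(rbinom(p * q, 1, ammgc:::sigmoid(logits + off)), p, q)
    pos <- ammgc:::positive_pairs(B)
    embs <- lapply(1:4, function(u) {
      E <- if (u == 1)
        abs(rbind(U %*% matrix(rnorm(r * d), r, d),
                  V %*% matrix(rnorm(r * d), r, d))) / 2
      else abs(matrix(rnorm((p + q) * d), p + q, d)) / 2
      make_emb(E, p, q, u)
    })
    att <- train_attention(embs, pos, NULL,
                           train_config(seed = s, d = d, epochs = 200L))
    mm <- export_attention_coefficients(att$params, embs)$modal_means
    if (which.max(mm) == 1L) wins <- wins + 1L
  }
  expect_equal(wins, 3L)
})

test_that("attention coefficient export tabulates magnitudes and means", {
  embs <- list(make_emb(diag(2), 1L, 1L, 1L))
  params <- list(list(W = matrix(c(1, -2), 1, 2), b = matrix(0, 1, 2)))
  out <- export_attention_coefficients(params, embs)
  expect_equal(out$table$magnitude, c(1, 2))
  expect_equal(unname(out$modal_means), 1.5)
  zero <- list(list(W = matrix(0, 1, 2), b = matrix(0, 1, 2)))
  expect_true(all(export_attention_coefficients(zero, embs)$table$weight == 0))
})
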