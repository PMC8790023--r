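#' Training configuration for the GCN and attention stages
#'
#' @param learning_rate Adam learning rate (default 0.01).
#' @param epochs number of full-graph training epochs (default 200).
#' @param neg_ratio negatives sampled per positive each epoch in the modal
#'   stage (default 1).
#' @param seed integer seed controlling initialization and sampling.
#' @param h1 first-layer width (default 128).
#' @param d embedding width of each modal (default 64, so the fused
#'   embedding is 4 x 64 = 256 wide).
#' @param layers number of graph-convolution layers, 1 to 6 (default 2).
#' @return a \code{train_config} list.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 200L,
                         neg_ratio = 1L, seed = 1L, h1 = 128L, d = 64L,
                         layers = 2L) {
  stopifnot(learning_rate > 0, epochs >= 1, neg_ratio >= 1,
            h1 >= 1, d >= 1, layers >= 1, layers <= 6)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 neg_ratio = as.integer(neg_ratio), seed = as.integer(seed),
                 h1 = as.integer(h1), d = as.integer(d),
                 layers = as.integer(layers)),
            class = "train_config")
}

#' Initialize GCN weights
#'
#' Glorot-uniform weight matrices for a stack of graph-convolution layers:
#' input width \code{d_u}, hidden width \code{h1}, output width \code{d}.
#' Draws from the current RNG stream.
#'
#' @param d_u input feature width.
#' @param h1 hidden width.
#' @param d output embedding width.
#' @param layers number of layers.
#' @return list with element \code{weights}, a list of weight matrices.
#' @export
gcn_init_params <- function(d_u, h1, d, layers = 2L) {
  widths <- c(d_u, rep(h1, max(layers - 1L, 0L)), d)
  if (layers == 1L) widths <- c(d_u, d)
  weights <- vector("list", layers)
  for (l in seq_len(layers))
    weights[[l]] <- glorot_uniform(widths[l], widths[l + 1L])
  list(weights = weights)
}

#' Graph-convolutional forward pass
#'
#' Propagates node features through ReLU graph-convolution layers:
#' \code{H_0 = X}, \code{H_l = ReLU(A_hat H_(l-1) W_l)}; with the default
#' two layers this is \code{E = ReLU(A_hat ReLU(A_hat X W_0) W_1)}. All
#' output entries are non-negative.
#'
#' @param X node feature matrix ((p+q) x d_u) or a \code{modal_input}.
#' @param A_hat normalized adjacency from \code{\link{normalize_adjacency}}.
#' @param params parameter list from \code{\link{gcn_init_params}}.
#' @return the embedding matrix E; when \code{X} is a \code{modal_input},
#'   a \code{modal_embedding} carrying \code{p} and \code{q}.
#' @export
gcn_forward <- function(X, A_hat, params) {
  modal <- inherits(X, "modal_input")
  Xm <- if (modal) X$X else as.matrix(X)
  if (nrow(Xm) != ncol(A_hat))
    stop(sprintf("feature rows (%d) must match adjacency size (%d)",
                 nrow(Xm), ncol(A_hat)))
  if (ncol(Xm) != nrow(params$weights[[1L]]))
    stop(sprintf("feature width (%d) must match W[1] rows (%d)",
                 ncol(Xm), nrow(params$weights[[1L]])))
  H <- Xm
  for (W in params$weights) H <- pmax(A_hat %*% H %*% W, 0)
  if (!modal) return(H)
  structure(list(modal_index = X$modal_index, E = H, p = X$p, q = X$q),
            class = "modal_embedding")
}

# Forward pass caching pre-activations and propagated activations,
# consumed by gcn_backward.
gcn_forward_cache <- function(Xm, A_hat, params) {
  L <- length(params$weights)
  AH <- vector("list", L)   # A_hat %*% H_(l-1)
  Z <- vector("list", L)    # pre-activation
  H <- Xm
  for (l in seq_len(L)) {
    AH[[l]] <- A_hat %*% H
    Z[[l]] <- AH[[l]] %*% params$weights[[l]]
    H <- pmax(Z[[l]], 0)
  }
  list(E = H, AH = AH, Z = Z)
}

# Backpropagate dL/dE through the cached forward pass; A_hat is symmetric.
gcn_backward <- function(G, A_hat, params, cache) {
  L <- length(params$weights)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dZ <- G * (cache$Z[[l]] > 0)
    grads[[l]] <- crossprod(cache$AH[[l]], dZ)
    if (l > 1L) G <- A_hat %*% tcrossprod(dZ, params$weights[[l]])
  }
  grads
}

#' Score a drug-miRNA pair from one modal's embeddings
#'
#' The association score is the sigmoid of the inner product between the
#' drug's embedding row and the miRNA's embedding row; it always lies in
#' (0, 1), and equals 0.5 when the embeddings are orthogonal.
#'
#' @param emb a \code{modal_embedding} (or any list with fields \code{E},
#'   \code{p}, \code{q}).
#' @param drug_index 1-based drug row index (1..p).
#' @param mirna_index 1-based miRNA index (1..q).
#' @return the association probability.
#' @export
modal_score <- function(emb, drug_index, mirna_index) {
  if (any(drug_index < 1L) || any(drug_index > emb$p))
    stop("drug index out of range")
  if (any(mirna_index < 1L) || any(mirna_index > emb$q))
    stop("miRNA index out of range")
  sigmoid(rowSums(emb$E[drug_index, , drop = FALSE] *
                  emb$E[emb$p + mirna_index, , drop = FALSE]))
}

#' Sample negative drug-miRNA pairs
#'
#' Draws \code{count} distinct pairs uniformly without replacement from the
#' zero entries of the association matrix. Deterministic when
#' \code{rng_seed} is supplied; otherwise draws from the current RNG
#' stream (how the per-epoch resampling inside training uses it).
#'
#' @param B p x q binary association matrix.
#' @param count number of pairs to draw.
#' @param rng_seed optional integer seed.
#' @return a \code{count} x 2 integer matrix of (drug, miRNA) indices.
#' @export
sample_negatives <- function(B, count, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  zeros <- which(B == 0)
  if (count > length(zeros))
    stop(sprintf("requested %d negatives but only %d zero pairs exist",
                 count, length(zeros)))
  pick <- if (count == 0L) integer(0) else
    zeros[sample.int(length(zeros), count)]
  p <- nrow(B)
  cbind(drug = (pick - 1L) %% p + 1L, mirna = (pick - 1L) %/% p + 1L)
}

# dL/dE for inner-product pair scoring under (optionally class-weighted)
# binary cross-entropy. pairs: n x 2 (drug, mirna); grad_logit: length n.
pair_grad_embedding <- function(E, p, pairs, grad_logit) {
  G <- matrix(0, nrow(E), ncol(E))
  di <- pairs[, 1L]
  mi <- p + pairs[, 2L]
  gd <- rowsum(grad_logit * E[mi, , drop = FALSE], di)
  G[as.integer(rownames(gd)), ] <- G[as.integer(rownames(gd)), ] + gd
  gm <- rowsum(grad_logit * E[di, , drop = FALSE], mi)
  G[as.integer(rownames(gm)), ] <- G[as.integer(rownames(gm)), ] + gm
  G
}

#' Train one modal graph-convolution sub-network
#'
#' Optimizes binary cross-entropy over the training positives plus
#' \code{neg_ratio} times as many negatives, resampled each epoch from the
#' zero pairs of the training association matrix, using full-batch Adam.
#' The loss is evaluated in logit form (softplus), mathematically identical
#' to the sigmoid/log composition but stable for large scores. Identical
#' seeds give identical results.
#'
#' @param X a \code{modal_input}.
#' @param A_hat normalized adjacency built from the training positives.
#' @param positives n x 2 matrix of (drug, miRNA) 1-based index pairs.
#' @param config a \code{\link{train_config}}.
#' @return list with \code{params} (trained weights), \code{embedding}
#'   (a \code{modal_embedding}), and \code{loss_history}.
#' @export
train_modal <- function(X, A_hat, positives, config = train_config()) {
  if (is.null(nrow(positives)) || nrow(positives) == 0L)
    stop("no training positives")
  p <- X$p; q <- X$q
  B_train <- matrix(0, p, q)
  B_train[positives] <- 1
  set.seed(config$seed)
  params <- gcn_init_params(X$d_u, config$h1, config$d, config$layers)
  state <- adam_init(params$weights)
  n_pos <- nrow(positives)
  n_neg <- config$neg_ratio * n_pos
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    negatives <- sample_negatives(B_train, n_neg)
    pairs <- rbind(positives, negatives)
    y <- c(rep(1, n_pos), rep(0, n_neg))
    cache <- gcn_forward_cache(X$X, A_hat, params)
    E <- cache$E
    z <- rowSums(E[pairs[, 1L], , drop = FALSE] *
                 E[p + pairs[, 2L], , drop = FALSE])
    loss <- mean(y * softplus(-z) + (1 - y) * softplus(z))
    if (!is.finite(loss)) stop("diverged")
    loss_history[epoch] <- loss
    grad_logit <- (sigmoid(z) - y) / length(y)
    G <- pair_grad_embedding(E, p, pairs, grad_logit)
    grads <- gcn_backward(G, A_hat, params, cache)
    step <- adam_step(params$weights, grads, state, config$learning_rate)
    params$weights <- step$params
    state <- step$state
  }
  emb <- structure(list(modal_index = X$modal_index,
                        E = gcn_forward_cache(X$X, A_hat, params)$E,
                        p = p, q = q),
                   class = "modal_embedding")
  list(params = params, embedding = emb, loss_history = loss_history)
}
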