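#' Per-modal attention vector
#'
#' Projects a modal embedding matrix to a 1 x d attention vector
#' \code{g = W E + b}. The attention parameters are deliberately small:
#' W is a 1 x (p+q) row vector and b a 1 x d row vector, so the projection
#' costs (p+q) + d parameters per modal instead of a full square map. The
#' vector is used raw (no softmax normalization).
#'
#' @param E (p+q) x d modal embedding matrix (or a \code{modal_embedding}).
#' @param W_u 1 x (p+q) numeric row vector.
#' @param b_u 1 x d numeric row vector.
#' @return the 1 x d attention vector \code{g}.
#' @export
attention_weights <- function(E, W_u, b_u) {
  if (inherits(E, "modal_embedding")) E <- E$E
  W_u <- matrix(W_u, nrow = 1L)
  b_u <- matrix(b_u, nrow = 1L)
  if (ncol(W_u) != nrow(E))
    stop(sprintf("W has %d columns but E has %d rows", ncol(W_u), nrow(E)))
  if (ncol(b_u) != ncol(E))
    stop(sprintf("b has %d columns but E has %d columns",
                 ncol(b_u), ncol(E)))
  W_u %*% E + b_u
}

#' Initialize attention parameters
#'
#' Glorot-uniform row vectors W_u and zero biases b_u for each modal,
#' drawn from the current RNG stream.
#'
#' @param n_nodes p + q.
#' @param d modal embedding width.
#' @param n_modals number of modals (default 4).
#' @return an \code{attention_params} list with one \code{list(W, b)} per
#'   modal.
#' @export
attention_init_params <- function(n_nodes, d, n_modals = 4L) {
  params <- lapply(seq_len(n_modals), function(u)
    list(W = glorot_uniform(1L, n_nodes), b = matrix(0, 1L, d)))
  class(params) <- "attention_params"
  params
}

#' Fuse modal embeddings into the attentive embedding
#'
#' Each modal embedding is rescaled dimension-wise by its attention vector
#' (\code{E_u diag(g_u)}) and the rescaled blocks are concatenated
#' horizontally into the (p+q) x (n_modals * d) attentive embedding Z.
#' Supplying \code{g_override} (e.g. all-ones vectors) bypasses the learned
#' attention; with all-ones this reproduces the unweighted-concatenation
#' ablation exactly.
#'
#' @param embeddings list of \code{modal_embedding} objects sharing p, q
#'   and d.
#' @param params an \code{attention_params} list (ignored when
#'   \code{g_override} is given).
#' @param g_override optional list of 1 x d vectors replacing the computed
#'   attention vectors.
#' @return an \code{attentive_embedding}: list with \code{Z}, \code{g}
#'   (list of attention vectors), \code{p}, \code{q}, \code{d}.
#' @export
fuse <- function(embeddings, params = NULL, g_override = NULL) {
  d <- ncol(embeddings[[1L]]$E)
  p <- embeddings[[1L]]$p; q <- embeddings[[1L]]$q
  for (emb in embeddings) {
    if (ncol(emb$E) != d) stop("modal embedding widths differ")
    if (emb$p != p || emb$q != q) stop("modal embedding node counts differ")
  }
  g <- if (!is.null(g_override)) {
    lapply(g_override, function(v) matrix(v, nrow = 1L))
  } else {
    lapply(seq_along(embeddings), function(u)
      attention_weights(embeddings[[u]]$E, params[[u]]$W, params[[u]]$b))
  }
  blocks <- lapply(seq_along(embeddings), function(u)
    embeddings[[u]]$E * rep(g[[u]], each = p + q))
  structure(list(Z = do.call(cbind, blocks), g = g, p = p, q = q, d = d),
            class = "attentive_embedding")
}

#' Final association score from the attentive embedding
#'
#' Sigmoid of the inner product between the attentive drug row and the
#' attentive miRNA row; strictly inside (0, 1) and monotone in the inner
#' product.
#'
#' @param Z an \code{attentive_embedding}.
#' @param drug_index 1-based drug indices.
#' @param mirna_index 1-based miRNA indices (recycled pairwise with
#'   \code{drug_index}).
#' @return association probabilities.
#' @export
final_score <- function(Z, drug_index, mirna_index) {
  if (any(drug_index < 1L) || any(drug_index > Z$p))
    stop("drug index out of range")
  if (any(mirna_index < 1L) || any(mirna_index > Z$q))
    stop("miRNA index out of range")
  sigmoid(rowSums(Z$Z[drug_index, , drop = FALSE] *
                  Z$Z[Z$p + mirna_index, , drop = FALSE]))
}

#' Positive-class weight for the imbalanced cross-entropy
#'
#' The fused scoring stage trains against (nearly) all p*q pairs, of which
#' only N are positives; the positive term of the loss is multiplied by
#' the negative:positive ratio \code{(p*q - N) / N} to balance the classes.
#'
#' @param p number of drugs.
#' @param q number of miRNAs.
#' @param N number of positive pairs (0 < N <= p*q).
#' @return the scalar weight.
#' @export
compute_pos_weight <- function(p, q, N) {
  if (N <= 0) stop("positive count must be positive")
  if (N > p * q) stop("positive count exceeds pair count")
  (p * q - N) / N
}

#' Train the attention fusion network
#'
#' Second training step: the four modal embeddings are frozen inputs (no
#' gradient reaches the GCN weights) and only the attention parameters
#' (W_u, b_u per modal) are optimized, under class-weighted binary
#' cross-entropy over every drug-miRNA pair except \code{excluded_pairs}
#' (the held-out test positives during cross-validation). Labels are 1 for
#' \code{train_positives} and 0 for all other included pairs; the positive
#' term is weighted by \code{\link{compute_pos_weight}} with N equal to
#' the training-positive count. Full-batch Adam; deterministic per seed.
#'
#' @param embeddings list of four frozen \code{modal_embedding} objects.
#' @param train_positives n x 2 (drug, miRNA) index pairs.
#' @param excluded_pairs m x 2 index pairs excluded from the loss, or NULL.
#' @param config a \code{\link{train_config}}.
#' @return list with \code{params} (\code{attention_params}),
#'   \code{attentive} (the fused \code{attentive_embedding}) and
#'   \code{loss_history}.
#' @export
train_attention <- function(embeddings, train_positives,
                            excluded_pairs = NULL,
                            config = train_config()) {
  if (is.null(nrow(train_positives)) || nrow(train_positives) == 0L)
    stop("no training positives")
  p <- embeddings[[1L]]$p; q <- embeddings[[1L]]$q
  d <- ncol(embeddings[[1L]]$E)
  n_modals <- length(embeddings)
  set.seed(config$seed)
  params <- attention_init_params(p + q, d, n_modals)
  flat <- unlist(lapply(params, function(pu) list(pu$W, pu$b)),
                 recursive = FALSE)
  state <- adam_init(flat)
  Y <- matrix(0, p, q)
  Y[train_positives] <- 1
  include <- matrix(TRUE, p, q)
  if (!is.null(excluded_pairs) && nrow(excluded_pairs) > 0L)
    include[excluded_pairs] <- FALSE
  n_inc <- sum(include)
  pw <- compute_pos_weight(p, q, nrow(train_positives))
  D <- lapply(embeddings, function(e) e$E[seq_len(p), , drop = FALSE])
  M <- lapply(embeddings, function(e) e$E[p + seq_len(q), , drop = FALSE])
  E_full <- lapply(embeddings, function(e) e$E)
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    g <- lapply(seq_len(n_modals), function(u)
      flat[[2L * u - 1L]] %*% E_full[[u]] + flat[[2L * u]])
    S <- matrix(0, p, q)
    for (u in seq_len(n_modals))
      S <- S + (D[[u]] * rep(g[[u]]^2, each = p)) %*% t(M[[u]])
    loss <- sum((pw * Y * softplus(-S) + (1 - Y) * softplus(S))[include]) /
      n_inc
    if (!is.finite(loss)) stop("diverged")
    loss_history[epoch] <- loss
    sig <- sigmoid(S)
    Gmat <- (pw * Y * (sig - 1) + (1 - Y) * sig) * include / n_inc
    grads <- vector("list", 2L * n_modals)
    for (u in seq_len(n_modals)) {
      g_grad <- 2 * g[[u]] * colSums(D[[u]] * (Gmat %*% M[[u]]))
      grads[[2L * u - 1L]] <- g_grad %*% t(E_full[[u]])
      grads[[2L * u]] <- g_grad
    }
    step <- adam_step(flat, grads, state, config$learning_rate)
    flat <- step$params
    state <- step$state
  }
  for (u in seq_len(n_modals)) {
    params[[u]]$W <- flat[[2L * u - 1L]]
    params[[u]]$b <- flat[[2L * u]]
  }
  list(params = params, attentive = fuse(embeddings, params),
       loss_history = loss_history)
}

#' Export attention coefficients per modal and dimension
#'
#' Tabulates the learned attention vectors: one row per (modal, dimension)
#' with the raw weight and its magnitude, suitable for a heatmap of modal
#' contributions, plus the per-modal mean magnitude.
#'
#' @param params trained \code{attention_params}.
#' @param embeddings the modal embeddings the attention was trained on.
#' @return list with \code{table} (data.frame: modal, dimension, weight,
#'   magnitude) and \code{modal_means} (named numeric vector of mean
#'   magnitudes).
#' @export
export_attention_coefficients <- function(params, embeddings) {
  g <- lapply(seq_along(embeddings), function(u)
    as.numeric(attention_weights(embeddings[[u]]$E,
                                 params[[u]]$W, params[[u]]$b)))
  d <- length(g[[1L]])
  tab <- data.frame(
    modal = rep(seq_along(g), each = d),
    dimension = rep(seq_len(d), times = length(g)),
    weight = unlist(g),
    magnitude = abs(unlist(g)))
  means <- vapply(g, function(v) mean(abs(v)), numeric(1))
  names(means) <- paste0("modal", seq_along(g))
  list(table = tab, modal_means = means)
}
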