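#' Fit the full attentive multimodal GCN model
#'
#' Runs the two-step training pipeline: (1) each selected modal's two-layer
#' graph-convolution sub-network is trained independently under binary
#' cross-entropy with per-epoch negative resampling; (2) the attention
#' network is trained on the frozen modal embeddings under class-weighted
#' cross-entropy over all pairs except \code{excluded_pairs}. The adjacency
#' is built from \code{train_positives} only, so held-out edges never leak
#' into message passing. Stage seeds are derived from \code{config$seed} by
#' fixed offsets (modal u uses seed + u, attention uses seed + 11), so each
#' stage can be reproduced in isolation.
#'
#' @param dataset an \code{\link{association_dataset}} (supplies ids and
#'   dimensions; its B is not consulted for training labels).
#' @param features a fully observed \code{\link{feature_set}} (impute
#'   first; see \code{\link{impute_feature_set}}).
#' @param train_positives n x 2 (drug, miRNA) index pairs used as training
#'   labels and graph edges; defaults to all positives of \code{dataset$B}.
#' @param excluded_pairs pairs excluded from the attention-stage loss
#'   (held-out test positives), or NULL.
#' @param config a \code{\link{train_config}}.
#' @param modals which of the four modals to use (default all).
#' @param use_attention logical; FALSE freezes every attention vector at 1,
#'   i.e. the unweighted-concatenation ablation.
#' @return an \code{ammgc_model}.
#' @export
ammgc_fit <- function(dataset, features, train_positives = NULL,
                      excluded_pairs = NULL, config = train_config(),
                      modals = 1:4, use_attention = TRUE) {
  if (is.null(train_positives))
    train_positives <- positive_pairs(dataset$B)
  p <- length(dataset$drug_ids); q <- length(dataset$mirna_ids)
  B_train <- matrix(0, p, q)
  B_train[train_positives] <- 1
  A_hat <- normalize_adjacency(build_adjacency(B_train))
  inputs <- build_modal_inputs(features)[modals]
  fits <- lapply(seq_along(inputs), function(k) {
    cfg <- config
    cfg$seed <- config$seed + modals[k]
    train_modal(inputs[[k]], A_hat, train_positives, cfg)
  })
  embeddings <- lapply(fits, `[[`, "embedding")
  if (use_attention) {
    cfg <- config
    cfg$seed <- config$seed + 11L
    att <- train_attention(embeddings, train_positives, excluded_pairs, cfg)
    attention <- att$params
    attentive <- att$attentive
    att_loss <- att$loss_history
  } else {
    attention <- NULL
    ones <- lapply(embeddings, function(e) rep(1, ncol(e$E)))
    attentive <- fuse(embeddings, g_override = ones)
    att_loss <- numeric(0)
  }
  structure(list(drug_ids = dataset$drug_ids, mirna_ids = dataset$mirna_ids,
                 p = p, q = q, config = config, modals = modals,
                 use_attention = use_attention,
                 modal_params = lapply(fits, `[[`, "params"),
                 modal_loss = lapply(fits, `[[`, "loss_history"),
                 embeddings = embeddings, attention = attention,
                 attentive = attentive, attention_loss = att_loss,
                 train_positives = train_positives),
            class = "ammgc_model")
}

#' @export
print.ammgc_model <- function(x, ...) {
  cat(sprintf(
    "ammgc_model: %d drugs x %d miRNAs, modals {%s}, attention %s\n",
    x$p, x$q, paste(x$modals, collapse = ","),
    if (x$use_attention) "on" else "off (unit weights)"))
  invisible(x)
}

# All (drug, miRNA) index pairs with B == 1, as an n x 2 matrix.
positive_pairs <- function(B) {
  idx <- which(B == 1)
  p <- nrow(B)
  cbind(drug = (idx - 1L) %% p + 1L, mirna = (idx - 1L) %/% p + 1L)
}

#' Full p x q matrix of association scores
#'
#' Sigmoid inner products between every attentive drug row and every
#' attentive miRNA row.
#'
#' @param model a fitted \code{ammgc_model}.
#' @return p x q numeric matrix of probabilities.
#' @export
score_matrix <- function(model) {
  Z <- model$attentive$Z
  S <- sigmoid(tcrossprod(Z[seq_len(model$p), , drop = FALSE],
                          Z[model$p + seq_len(model$q), , drop = FALSE]))
  dimnames(S) <- list(model$drug_ids, model$mirna_ids)
  S
}

#' @export
predict.ammgc_model <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) return(score_matrix(object))
  final_score(object$attentive, pairs[, 1L], pairs[, 2L])
}

#' Rank unlabeled drug-miRNA pairs by predicted score
#'
#' Scores every zero pair of the association matrix with a model trained
#' on all known positives and returns the top candidates in descending
#' score order; ties are broken lexicographically by (drug_id, mirna_id)
#' so rankings are deterministic.
#'
#' @param model a fitted \code{ammgc_model}.
#' @param dataset the \code{\link{association_dataset}} whose zero pairs
#'   are the candidates.
#' @param top_k number of rows to return; truncated with a warning when it
#'   exceeds the number of zero pairs.
#' @return data.frame with columns drug_id, mirna_id, score, rank.
#' @export
rank_candidates <- function(model, dataset, top_k) {
  S <- score_matrix(model)
  zero_idx <- which(dataset$B == 0)
  if (top_k > length(zero_idx)) {
    warning(sprintf("top_k (%d) exceeds zero-pair count (%d); truncating",
                    top_k, length(zero_idx)))
    top_k <- length(zero_idx)
  }
  p <- nrow(dataset$B)
  i <- (zero_idx - 1L) %% p + 1L
  j <- (zero_idx - 1L) %/% p + 1L
  tab <- data.frame(drug_id = dataset$drug_ids[i],
                    mirna_id = dataset$mirna_ids[j],
                    score = S[zero_idx],
                    stringsAsFactors = FALSE)
  ord <- order(-tab$score, tab$drug_id, tab$mirna_id)
  tab <- tab[ord[seq_len(top_k)], , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Save / load a trained model checkpoint
#'
#' Serializes the full model (weights, attention parameters, config,
#' identifier lists) so that predictions can be reproduced bit-exactly.
#'
#' @param model an \code{ammgc_model}.
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  model <- readRDS(path)
  if (!inherits(model, "ammgc_model")) stop("not an ammgc checkpoint")
  model
}
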