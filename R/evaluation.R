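#' Partition positive pairs into cross-validation folds
#'
#' A seeded uniform shuffle of the positives split into k near-equal test
#' subsets (sizes differ by at most one); each fold's training set is the
#' complement of its test set. The union of test sets over folds is the
#' full positive list, pairwise disjoint.
#'
#' @param positives n x 2 (drug, miRNA) index pairs.
#' @param k number of folds (default 5).
#' @param rng_seed integer seed.
#' @return list of \code{fold_split} objects with fields
#'   \code{fold_index}, \code{train_positives}, \code{test_positives}.
#' @export
make_folds <- function(positives, k = 5L, rng_seed = 1L) {
  n <- nrow(positives)
  if (k < 2L) stop("need at least 2 folds")
  if (n < k) stop("fewer positives than folds")
  set.seed(rng_seed)
  perm <- sample.int(n)
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f)
    structure(list(fold_index = f,
                   train_positives = positives[assignment != f, ,
                                               drop = FALSE],
                   test_positives = positives[assignment == f, ,
                                              drop = FALSE]),
              class = "fold_split"))
}

#' Ranking and classification metrics for link prediction
#'
#' AUC is the probability that a uniformly chosen positive outscores a
#' uniformly chosen negative, with ties counted one half (computed from
#' mean ranks, identical to the pairwise Mann-Whitney count). AUPR is the
#' step-wise average precision (no linear interpolation between
#' precision-recall points). F1, accuracy and recall are computed after
#' binarizing scores at \code{threshold}.
#'
#' @param scores numeric vector of predicted probabilities.
#' @param labels binary vector (same length).
#' @param threshold classification cut-off (default 0.5).
#' @return one-row data.frame with columns aupr, auc, f1, acc, rec.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  l_sorted <- labels[ord]
  s_sorted <- scores[ord]
  ends <- cumsum(rle(s_sorted)$lengths)
  tp <- cumsum(l_sorted)[ends]
  fp <- cumsum(1 - l_sorted)[ends]
  prec <- tp / (tp + fp)
  rec_curve <- tp / n_pos
  aupr <- sum(diff(c(0, rec_curve)) * prec)
  pred <- as.numeric(scores >= threshold)
  tp_c <- sum(pred == 1 & labels == 1)
  fp_c <- sum(pred == 1 & labels == 0)
  fn_c <- sum(pred == 0 & labels == 1)
  precision <- if (tp_c + fp_c == 0) 0 else tp_c / (tp_c + fp_c)
  recall <- tp_c / (tp_c + fn_c)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  acc <- mean(pred == labels)
  data.frame(aupr = aupr, auc = auc, f1 = f1, acc = acc, rec = recall)
}

#' Evaluate one cross-validation fold
#'
#' Scores the fold's held-out test positives against every pair that was
#' not a training positive (the full imbalanced candidate universe, not a
#' subsampled negative set) and computes the five metrics.
#'
#' @param scores p x q matrix of predicted probabilities from a model
#'   trained with the fold's test positives excluded.
#' @param split a \code{fold_split}.
#' @param B the p x q association matrix (dimension source).
#' @param threshold classification cut-off.
#' @return one-row metric data.frame (see \code{\link{compute_metrics}}).
#' @export
evaluate_fold <- function(scores, split, B, threshold = 0.5) {
  p <- nrow(B); q <- ncol(B)
  is_train <- matrix(FALSE, p, q)
  is_train[split$train_positives] <- TRUE
  if (any(is_train[split$test_positives]))
    stop("train and test positives overlap")
  labels <- matrix(0, p, q)
  labels[split$test_positives] <- 1
  keep <- !is_train
  compute_metrics(scores[keep], labels[keep], threshold)
}

#' Repeated k-fold cross-validation of the full pipeline
#'
#' For each repeat, the known positives are re-partitioned into k folds;
#' for each fold the complete two-step model is retrained with the fold's
#' test positives removed from the adjacency, the sub-network losses and
#' the attention loss, then evaluated against all non-training pairs.
#' Metrics are aggregated as mean and standard deviation over the
#' k x repeats fold-evaluations. Fully deterministic given
#' \code{config$seed}: fold assignment for repeat r uses
#' seed + 1000 * r, and the model for fold f of repeat r uses
#' seed + 1000 * r + 20 * f.
#'
#' @param dataset an \code{\link{association_dataset}}.
#' @param features a fully observed \code{\link{feature_set}}.
#' @param config a \code{\link{train_config}}.
#' @param k folds per repeat (default 5).
#' @param repeats number of re-partitions (default 10).
#' @param threshold classification cut-off for F1/ACC/REC.
#' @param modals which modals to use.
#' @param use_attention logical; FALSE runs the unit-weight ablation.
#' @return a \code{metric_report}: list with \code{summary} (metric, mean,
#'   sd), \code{per_fold} (one row per fold-evaluation), \code{n_folds},
#'   \code{n_repeats}.
#' @export
cross_validate <- function(dataset, features, config = train_config(),
                           k = 5L, repeats = 10L, threshold = 0.5,
                           modals = 1:4, use_attention = TRUE) {
  positives <- positive_pairs(dataset$B)
  rows <- vector("list", k * repeats)
  idx <- 0L
  for (r in seq_len(repeats)) {
    folds <- make_folds(positives, k, config$seed + 1000L * r)
    for (f in seq_len(k)) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * r + 20L * f
      model <- ammgc_fit(dataset, features,
                         train_positives = folds[[f]]$train_positives,
                         excluded_pairs = folds[[f]]$test_positives,
                         config = cfg, modals = modals,
                         use_attention = use_attention)
      m <- evaluate_fold(score_matrix(model), folds[[f]], dataset$B,
                         threshold)
      m$repeat_index <- r
      m$fold_index <- f
      idx <- idx + 1L
      rows[[idx]] <- m
    }
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("aupr", "auc", "f1", "acc", "rec")
  summary <- data.frame(
    metric = toupper(metrics),
    mean = vapply(metrics, function(m) mean(per_fold[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(summary = summary, per_fold = per_fold,
                 n_folds = as.integer(k), n_repeats = as.integer(repeats)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s) (%d evaluations)\n",
              x$n_folds, x$n_repeats, nrow(x$per_fold)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-5s %.4f ± %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Write a metric report as a delimited table
#' @param report a \code{metric_report}.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_metric_report <- function(report, path, sep = "\t") {
  utils::write.table(report$summary, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
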