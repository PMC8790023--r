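#' Specification for the synthetic bipartite generator
#'
#' Describes a sparse drug-miRNA association graph with planted low-rank
#' structure plus four feature blocks whose columns carry signal about the
#' latent factors. Association logits are a scaled inner product of latent
#' factors with an offset solved so the expected edge density matches
#' \code{density}; features are noisy transforms of the same factors, so a
#' model that recovers the factors can predict held-out edges.
#'
#' @param p,q numbers of drugs and miRNAs.
#' @param latent_rank rank r of the planted factors (default 4).
#' @param density target fraction of positive pairs (default 0.04,
#'   matching the sparsity regime of real resistance data, which is filled
#'   at roughly 4 percent).
#' @param feature_noise standard deviation of additive feature noise
#'   (default 0.1, a low-noise regime).
#' @param informative length-4 logical, one per modal; a modal marked
#'   FALSE has the latent input of its feature blocks replaced by fresh
#'   noise. Because the four modals share feature blocks pairwise, a block
#'   is informative when any modal using it is informative (see the
#'   package vignette).
#' @param seed integer seed; identical specs give identical outputs.
#' @param profile feature widths: \code{"full"} uses the real-data widths
#'   (920 / 85 / 172 / 2587), \code{"small"} a fast profile
#'   (64 / 16 / 32 / 128).
#' @param mask_fraction fraction of miRNA rows flagged unknown in each
#'   miRNA feature block, to exercise imputation (default 0.15).
#' @param signal_scale standard-deviation scale of the planted logits
#'   (default 2; larger values plant a stronger, easier signal).
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(p = 30L, q = 40L, latent_rank = 4L,
                           density = 0.04, feature_noise = 0.1,
                           informative = rep(TRUE, 4L), seed = 1L,
                           profile = c("small", "full"),
                           mask_fraction = 0.15, signal_scale = 2) {
  profile <- match.arg(profile)
  stopifnot(density > 0, density < 1, latent_rank >= 1, feature_noise >= 0,
            length(informative) == 4L, mask_fraction >= 0, mask_fraction < 1)
  widths <- if (profile == "full") c(d1 = 920L, d2 = 85L, m1 = 172L,
                                     m2 = 2587L)
            else c(d1 = 64L, d2 = 16L, m1 = 32L, m2 = 128L)
  structure(list(p = as.integer(p), q = as.integer(q),
                 latent_rank = as.integer(latent_rank), density = density,
                 feature_noise = feature_noise,
                 informative = as.logical(informative),
                 seed = as.integer(seed), profile = profile,
                 widths = widths, mask_fraction = mask_fraction,
                 signal_scale = signal_scale),
            class = "synthetic_spec")
}

# Offset c such that mean(sigmoid(logits + c)) == density, by bisection.
solve_density_offset <- function(logits, density, tol = 1e-10) {
  lo <- -40; hi <- 40
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (mean(sigmoid(logits + mid)) < density) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic dataset with planted low-rank structure
#'
#' Draws latent factors U (p x r) and V (q x r) from a standard normal,
#' forms pair logits as a scaled, density-calibrated U V', samples the
#' binary association matrix Bernoulli-wise, and derives the four feature
#' blocks from the factors: fingerprints are a median-binarized random
#' projection of U; SMILES strings come from a toy grammar with lengths
#' tracking U's first factor and are label-encoded; expression profiles are
#' a non-negative-clipped affine image of V plus noise; GO-style
#' similarities are the cosine similarity V V' mapped to [0, 1] and
#' padded/projected to the block width. Non-informative blocks use fresh
#' noise factors instead. A fraction of miRNA rows is masked unknown (NA)
#' to exercise imputation downstream.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{dataset} (an
#'   \code{\link{association_dataset}}), \code{features} (a
#'   \code{\link{feature_set}} with NA placeholder rows where masked),
#'   \code{smiles} (named character vector), \code{vocab}, and the ground
#'   truth factors \code{U}, \code{V}.
#' @export
generate_synthetic <- function(spec) {
  set.seed(spec$seed)
  p <- spec$p; q <- spec$q; r <- spec$latent_rank
  U <- matrix(stats::rnorm(p * r), p, r)
  V <- matrix(stats::rnorm(q * r), q, r)
  raw <- tcrossprod(U, V) / sqrt(r)
  logits <- spec$signal_scale * raw
  offset <- solve_density_offset(logits, spec$density)
  prob <- sigmoid(logits + offset)
  B <- matrix(stats::rbinom(p * q, 1L, prob), p, q)
  if (sum(B) == 0) {
    B <- matrix(stats::rbinom(p * q, 1L, prob), p, q)
    if (sum(B) == 0)
      stop("density unreachable: no positive pairs sampled")
  }
  inf <- spec$informative
  block_inf <- c(d1 = inf[1] || inf[2], d2 = inf[3] || inf[4],
                 m1 = inf[1] || inf[3], m2 = inf[2] || inf[4])
  src <- function(base, informative)
    if (informative) base else
      matrix(stats::rnorm(length(base)), nrow(base), ncol(base))
  w <- spec$widths
  noise <- function(n, k) matrix(stats::rnorm(n * k, 0, spec$feature_noise),
                                 n, k)

  # drug fingerprints: median-binarized random projection of U
  Ud1 <- src(U, block_inf["d1"])
  proj_d1 <- Ud1 %*% matrix(stats::rnorm(r * w["d1"]), r, w["d1"]) +
    noise(p, w["d1"])
  X_d1 <- sweep(proj_d1, 2, apply(proj_d1, 2, stats::median), ">=") * 1

  # SMILES: toy grammar, lengths tracking U's first factor
  Ud2 <- src(U, block_inf["d2"])
  len <- 5L + as.integer(round(85 * rank(Ud2[, 1L]) / (p + 1L)))
  smiles <- generate_smiles_like(p, rng_seed = NULL, lengths = len)
  names(smiles) <- paste0("drug", seq_len(p))
  vocab <- build_vocabulary(smiles)
  X_d2 <- encode_smiles_matrix(smiles, vocab, max_len = w["d2"])

  # miRNA expression: non-negative-clipped affine image of V
  Vm1 <- src(V, block_inf["m1"])
  X_m1 <- pmax(Vm1 %*% matrix(stats::rnorm(r * w["m1"]), r, w["m1"]) +
                 noise(q, w["m1"]), 0)

  # miRNA GO-style similarity: cosine similarity mapped to [0, 1]
  Vm2 <- src(V, block_inf["m2"])
  Vn <- Vm2 / sqrt(rowSums(Vm2^2))
  sim01 <- (tcrossprod(Vn) + 1) / 2
  X_m2 <- if (q >= w["m2"]) {
    sim01 %*% matrix(stats::rnorm(q * w["m2"], 0, 1 / sqrt(q)), q, w["m2"])
  } else {
    cbind(sim01, matrix(0, q, w["m2"] - q))
  }
  X_m2 <- pmin(pmax(X_m2 + noise(q, w["m2"]), 0), 1)

  mask_m1 <- stats::runif(q) >= spec$mask_fraction
  mask_m2 <- stats::runif(q) >= spec$mask_fraction
  if (!any(mask_m1)) mask_m1[1L] <- TRUE
  if (!any(mask_m2)) mask_m2[1L] <- TRUE
  X_m1[!mask_m1, ] <- NA_real_
  X_m2[!mask_m2, ] <- NA_real_

  dataset <- association_dataset(paste0("drug", seq_len(p)),
                                 paste0("mirna", seq_len(q)), B)
  features <- feature_set(X_d1, X_d2, X_m1, X_m2, mask_m1, mask_m2)
  list(dataset = dataset, features = features, smiles = smiles,
       vocab = vocab, U = U, V = V, spec = spec)
}

#' Generate SMILES-like strings from a toy branching grammar
#'
#' Emits strings over the alphabet C, O, N, =, (, ), 1, 2, c, n with
#' lengths between 5 and 90: atoms are drawn at random, double bonds ("=")
#' are always followed by an atom, parentheses open and close in balance,
#' and ring digits appear in pairs. The strings are chemically meaningless
#' by design; they exercise the label-encoding path, including truncation
#' for strings longer than the encoding width.
#'
#' @param n number of strings.
#' @param rng_seed integer seed, or NULL to draw from the current stream.
#' @param lengths optional integer vector of target lengths (clamped to
#'   5..90); drawn uniformly when omitted.
#' @return character vector of length n.
#' @export
generate_smiles_like <- function(n, rng_seed = 1L, lengths = NULL) {
  if (n < 1L) stop("need n >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(lengths)) lengths <- sample(5:90, n, replace = TRUE)
  lengths <- pmin(pmax(as.integer(lengths), 5L), 90L)
  atoms <- c("C", "O", "N", "c", "n")
  vapply(seq_len(n), function(i) {
    target <- lengths[i]
    out <- character(0)
    open <- 0L
    ring_open <- c(`1` = FALSE, `2` = FALSE)
    emit_atom <- function() sample(atoms, 1L)
    out <- c(out, emit_atom())
    while (length(out) < target) {
      room <- target - length(out)
      choice <- sample(c("atom", "bond", "branch", "ring"), 1L,
                       prob = c(0.55, 0.15, 0.15, 0.15))
      if (choice == "bond" && room >= 2L) {
        out <- c(out, "=", emit_atom())
      } else if (choice == "branch" && room >= 3L) {
        out <- c(out, "(", emit_atom(), ")")
      } else if (choice == "ring" && any(!ring_open)) {
        digit <- names(ring_open)[!ring_open][1L]
        ring_open[digit] <- TRUE
        out <- c(out, digit)
      } else if (choice == "ring" && any(ring_open)) {
        digit <- names(ring_open)[ring_open][1L]
        ring_open[digit] <- FALSE
        out <- c(out, digit)
      } else {
        out <- c(out, emit_atom())
      }
    }
    paste(out[seq_len(target)], collapse = "")
  }, character(1))
}

#' Write a synthetic dataset in the package's input formats
#'
#' Emits the five delimited files the loaders read: an association edge
#' list, the fingerprint / expression / GO-similarity feature tables (with
#' masked miRNA rows omitted, exercising the imputation path on reload)
#' and a two-column SMILES table.
#'
#' @param sim result of \code{\link{generate_synthetic}}.
#' @param dir output directory (created if needed).
#' @param sep field delimiter.
#' @return named character vector of the five file paths.
#' @export
write_synthetic_dataset <- function(sim, dir, sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             fingerprints = file.path(dir, "fingerprints.tsv"),
             smiles = file.path(dir, "smiles.tsv"),
             expression = file.path(dir, "expression.tsv"),
             go_similarity = file.path(dir, "go_similarity.tsv"))
  write_associations(sim$dataset, paths["associations"], sep)
  write_table <- function(X, ids, keep, path) {
    tab <- data.frame(id = ids[keep],
                      X[keep, , drop = FALSE],
                      check.names = FALSE)
    names(tab) <- c("id", paste0("f", seq_len(ncol(X))))
    utils::write.table(tab, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  fs <- sim$features
  write_table(fs$X_d1, sim$dataset$drug_ids, rep(TRUE, nrow(fs$X_d1)),
              paths["fingerprints"])
  utils::write.table(
    data.frame(drug_id = sim$dataset$drug_ids, smiles = unname(sim$smiles)),
    paths["smiles"], sep = sep, quote = FALSE, row.names = FALSE)
  write_table(fs$X_m1, sim$dataset$mirna_ids, fs$known_mask_m1,
              paths["expression"])
  write_table(fs$X_m2, sim$dataset$mirna_ids, fs$known_mask_m2,
              paths["go_similarity"])
  paths
}
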