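#' Construct an association dataset
#'
#' Bundles an ordered drug identifier list, an ordered miRNA identifier list
#' and the binary association matrix \code{B} (drugs in rows, miRNAs in
#' columns) into a validated object. Row \code{i} of \code{B} corresponds to
#' \code{drug_ids[i]}, column \code{j} to \code{mirna_ids[j]}.
#'
#' @param drug_ids character vector of unique drug identifiers (length p).
#' @param mirna_ids character vector of unique miRNA identifiers (length q).
#' @param B p x q matrix with entries in \{0, 1\}.
#' @return An object of class \code{association_dataset} with fields
#'   \code{drug_ids}, \code{mirna_ids} and \code{B}.
#' @export
association_dataset <- function(drug_ids, mirna_ids, B) {
  drug_ids <- as.character(drug_ids)
  mirna_ids <- as.character(mirna_ids)
  if (length(drug_ids) < 1L || length(mirna_ids) < 1L)
    stop("need at least one drug and one miRNA")
  if (anyDuplicated(drug_ids)) stop("duplicate drug identifiers")
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA identifiers")
  B <- as.matrix(B)
  if (nrow(B) != length(drug_ids) || ncol(B) != length(mirna_ids))
    stop(sprintf("B must be %d x %d, got %d x %d",
                 length(drug_ids), length(mirna_ids), nrow(B), ncol(B)))
  if (!all(B %in% c(0, 1))) stop("B must be binary")
  storage.mode(B) <- "double"
  dimnames(B) <- list(drug_ids, mirna_ids)
  structure(list(drug_ids = drug_ids, mirna_ids = mirna_ids, B = B),
            class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "association_dataset: %d drugs x %d miRNAs, %d associations (fill %.2f%%)\n",
    length(x$drug_ids), length(x$mirna_ids), sum(x$B),
    100 * mean(x$B)))
  invisible(x)
}

#' Load a drug-miRNA association edge list
#'
#' Reads a two-column delimited edge list (drug_id, mirna_id) and assembles
#' the binary association matrix. Duplicate edges collapse to a single 1.
#' When identifier universes are supplied, nodes absent from the edge list
#' are retained as all-zero rows/columns; otherwise the universes are taken
#' as the distinct identifiers in file order of first appearance.
#'
#' @param path path to the edge-list file.
#' @param drug_universe optional character vector covering every drug id in
#'   the file.
#' @param mirna_universe optional character vector covering every miRNA id.
#' @param sep field delimiter, \code{"\t"} (default) or \code{","}.
#' @param header logical; does the file carry a header row? Default
#'   \code{FALSE}.
#' @return an \code{\link{association_dataset}}.
#' @export
load_associations <- function(path, drug_universe = NULL,
                              mirna_universe = NULL, sep = "\t",
                              header = FALSE) {
  if (length(readLines(path, n = 1L)) == 0L) stop("no associations")
  edges <- utils::read.table(path, sep = sep, header = header,
                             colClasses = "character", quote = "",
                             comment.char = "")
  if (ncol(edges) != 2L)
    stop(sprintf("edge list must have 2 columns, found %d", ncol(edges)))
  names(edges) <- c("drug_id", "mirna_id")
  if (nrow(edges) == 0L) stop("no associations")
  if (is.null(drug_universe)) drug_universe <- unique(edges$drug_id)
  if (is.null(mirna_universe)) mirna_universe <- unique(edges$mirna_id)
  bad_d <- setdiff(edges$drug_id, drug_universe)
  if (length(bad_d))
    stop(sprintf("drug id not in universe: %s", bad_d[1L]))
  bad_m <- setdiff(edges$mirna_id, mirna_universe)
  if (length(bad_m))
    stop(sprintf("miRNA id not in universe: %s", bad_m[1L]))
  B <- matrix(0, length(drug_universe), length(mirna_universe))
  i <- match(edges$drug_id, drug_universe)
  j <- match(edges$mirna_id, mirna_universe)
  B[cbind(i, j)] <- 1
  association_dataset(drug_universe, mirna_universe, B)
}

#' Write an association dataset as an edge list
#'
#' Emits one (drug_id, mirna_id) row per positive entry of \code{B}, in
#' row-major order. Reloading with the same universes reproduces \code{B}
#' exactly.
#'
#' @param dataset an \code{\link{association_dataset}}.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_associations <- function(dataset, path, sep = "\t") {
  idx <- which(t(dataset$B) == 1)  # transpose -> row-major over B
  q <- length(dataset$mirna_ids)
  i <- (idx - 1L) %/% q + 1L
  j <- (idx - 1L) %% q + 1L
  utils::write.table(
    data.frame(drug_id = dataset$drug_ids[i],
               mirna_id = dataset$mirna_ids[j]),
    path, sep = sep, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load an id-keyed numeric feature table
#'
#' Reads a delimited table with a header row, an identifier column and a
#' fixed number of numeric feature columns, and reorders its rows to match
#' \code{ids}. Entities absent from the file receive an \code{NA}
#' placeholder row and a \code{FALSE} entry in the returned mask; they are
#' later filled by \code{\link{impute_missing}}.
#'
#' @param path path to the table.
#' @param ids character vector giving the required row order.
#' @param expected_cols required number of feature columns.
#' @param id_column name of the identifier column (default first column).
#' @param sep field delimiter.
#' @return list with \code{matrix} (length(ids) x expected_cols) and
#'   \code{known_mask} (logical, TRUE where the row was observed).
#' @export
load_feature_table <- function(path, ids, expected_cols,
                               id_column = NULL, sep = "\t") {
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (is.null(id_column)) id_column <- names(tab)[1L]
  if (!id_column %in% names(tab))
    stop(sprintf("id column '%s' not found", id_column))
  feat_cols <- setdiff(names(tab), id_column)
  if (length(feat_cols) != expected_cols)
    stop(sprintf("expected %d feature columns, found %d",
                 expected_cols, length(feat_cols)))
  row_ids <- tab[[id_column]]
  vals <- matrix(NA_real_, nrow(tab), length(feat_cols))
  for (k in seq_along(feat_cols)) {
    v <- suppressWarnings(as.numeric(tab[[feat_cols[k]]]))
    bad <- which(is.na(v) & !tab[[feat_cols[k]]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("unparseable numeric value at row %d, column '%s'",
                   bad[1L], feat_cols[k]))
    vals[, k] <- v
  }
  pos <- match(ids, row_ids)
  known <- !is.na(pos)
  out <- matrix(NA_real_, length(ids), length(feat_cols))
  out[known, ] <- vals[pos[known], , drop = FALSE]
  rownames(out) <- ids
  list(matrix = out, known_mask = known)
}

#' Impute missing feature rows by the column means of observed rows
#'
#' Rows flagged unknown are replaced by the column-wise mean computed over
#' the known rows; known rows pass through unchanged. The operation is
#' idempotent and leaves the column means over originally-known rows
#' untouched.
#'
#' @param matrix n x k numeric matrix.
#' @param known_mask logical vector of length n; TRUE marks observed rows.
#' @return the imputed n x k matrix (no missing values).
#' @export
impute_missing <- function(matrix, known_mask) {
  if (length(known_mask) != nrow(matrix))
    stop("known_mask length must equal row count")
  if (!any(known_mask)) stop("nothing to impute from")
  if (any(!known_mask)) {
    mu <- colMeans(matrix[known_mask, , drop = FALSE])
    matrix[!known_mask, ] <- rep(mu, each = sum(!known_mask))
  }
  matrix
}

#' Construct a multimodal feature set
#'
#' Holds the four raw feature blocks: drug substructure fingerprints
#' (binary, 920 columns at full scale), label-encoded SMILES (non-negative
#' integers), miRNA expression profiles and miRNA GO-based similarity
#' scores, together with per-miRNA masks marking observed (not imputed)
#' rows.
#'
#' @param X_d1 p x a binary fingerprint matrix.
#' @param X_d2 p x b non-negative-integer SMILES encoding matrix.
#' @param X_m1 q x c real expression matrix.
#' @param X_m2 q x e real GO-similarity matrix.
#' @param known_mask_m1,known_mask_m2 logical length-q masks; default all
#'   TRUE.
#' @return an object of class \code{feature_set}.
#' @export
feature_set <- function(X_d1, X_d2, X_m1, X_m2,
                        known_mask_m1 = rep(TRUE, nrow(X_m1)),
                        known_mask_m2 = rep(TRUE, nrow(X_m2))) {
  X_d1 <- as.matrix(X_d1); X_d2 <- as.matrix(X_d2)
  X_m1 <- as.matrix(X_m1); X_m2 <- as.matrix(X_m2)
  if (nrow(X_d1) != nrow(X_d2)) stop("drug blocks disagree on p")
  if (nrow(X_m1) != nrow(X_m2)) stop("miRNA blocks disagree on q")
  if (!all(X_d1 %in% c(0, 1))) stop("fingerprints must be binary")
  d2 <- X_d2[!is.na(X_d2)]
  if (any(d2 < 0) || any(d2 != floor(d2)))
    stop("SMILES encodings must be non-negative integers")
  structure(list(X_d1 = X_d1, X_d2 = X_d2, X_m1 = X_m1, X_m2 = X_m2,
                 known_mask_m1 = as.logical(known_mask_m1),
                 known_mask_m2 = as.logical(known_mask_m2)),
            class = "feature_set")
}

#' Impute every missing miRNA feature row in a feature set
#'
#' Applies \code{\link{impute_missing}} to both miRNA blocks using their
#' masks. Drug blocks must already be complete: the pipeline treats a
#' missing drug feature row as an error rather than imputing it.
#'
#' @param fs a \code{\link{feature_set}}.
#' @return the feature set with fully observed matrices.
#' @export
impute_feature_set <- function(fs) {
  if (anyNA(fs$X_d1) || anyNA(fs$X_d2))
    stop("drug feature rows must be complete")
  fs$X_m1 <- impute_missing(fs$X_m1, fs$known_mask_m1)
  fs$X_m2 <- impute_missing(fs$X_m2, fs$known_mask_m2)
  fs
}

#' Write ranked predictions to a delimited file
#'
#' @param predictions data frame with columns drug_id, mirna_id, score,
#'   rank (descending score).
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_predictions <- function(predictions, path, sep = "\t") {
  utils::write.table(predictions, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
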