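#' Build the bipartite adjacency matrix
#'
#' Embeds the p x q association matrix B in the (p+q) x (p+q) block form
#' \code{A = [[0, B], [B', 0]]}: drugs occupy the first p rows/columns,
#' miRNAs the last q. A is symmetric with zero diagonal, and the
#' drug-drug and miRNA-miRNA blocks are zero.
#'
#' @param B p x q binary matrix.
#' @return (p+q) x (p+q) binary symmetric matrix.
#' @export
build_adjacency <- function(B) {
  B <- as.matrix(B)
  if (!all(B %in% c(0, 1))) stop("B must be binary")
  p <- nrow(B); q <- ncol(B)
  A <- matrix(0, p + q, p + q)
  A[seq_len(p), p + seq_len(q)] <- B
  A[p + seq_len(q), seq_len(p)] <- t(B)
  A
}

#' Symmetric degree normalization with self-loops
#'
#' Adds a self-loop to every node (including isolated ones, which then act
#' as identity rows) and computes
#' \code{A_hat = D^(-1/2) (A + I) D^(-1/2)} where D is the diagonal degree
#' matrix of A + I. Every degree is at least 1, so the normalization never
#' divides by zero. A_hat is symmetric, non-negative, and its spectrum
#' lies in [-1, 1].
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @return the normalized adjacency \code{A_hat}.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (any(diag(A) != 0)) stop("A must have zero diagonal")
  if (!isTRUE(all.equal(A, t(A)))) stop("A must be symmetric")
  A_tilde <- A + diag(nrow(A))
  d_inv_sqrt <- 1 / sqrt(rowSums(A_tilde))
  A_tilde * outer(d_inv_sqrt, d_inv_sqrt)
}
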