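#' Build a SMILES character vocabulary
#'
#' Enumerates the distinct single characters of the input strings in order
#' of first appearance and assigns integer codes starting at 1. Code 0 is
#' reserved for padding and never maps to a token. The construction is
#' deterministic and independent of any random seed.
#'
#' @param smiles_list non-empty character vector of SMILES strings.
#' @return a named integer vector (class \code{smiles_vocabulary}) mapping
#'   token to code.
#' @export
build_vocabulary <- function(smiles_list) {
  if (length(smiles_list) == 0L) stop("empty SMILES list")
  tokens <- unique(unlist(strsplit(smiles_list, "", fixed = TRUE),
                          use.names = FALSE))
  vocab <- seq_along(tokens)
  names(vocab) <- tokens
  class(vocab) <- "smiles_vocabulary"
  vocab
}

#' Encode a SMILES string as a fixed-length integer vector
#'
#' Each character maps to its vocabulary code; the result is right-padded
#' with zeros to \code{max_len} and truncated (keeping the prefix) beyond
#' it. Characters outside the vocabulary receive a shared "unknown" code of
#' \code{max(vocab) + 1}, with a warning, so unusual strings encode
#' deterministically instead of failing.
#'
#' @param smiles a single SMILES string.
#' @param vocab a \code{\link{build_vocabulary}} result.
#' @param max_len output length (default 85, matching the drug
#'   representation width used throughout the package).
#' @return integer vector of length \code{max_len}.
#' @export
encode_smiles <- function(smiles, vocab, max_len = 85L) {
  if (!is.character(smiles) || length(smiles) != 1L || nchar(smiles) == 0L)
    stop("empty SMILES")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  if (length(chars) > max_len) chars <- chars[seq_len(max_len)]
  codes <- unname(vocab[chars])
  unk <- is.na(codes)
  if (any(unk)) {
    warning(sprintf("unknown SMILES token(s) %s encoded with code %d",
                    paste(unique(chars[unk]), collapse = ""),
                    max(vocab) + 1L))
    codes[unk] <- max(vocab) + 1L
  }
  c(codes, integer(max_len - length(codes)))
}

#' Decode an encoded SMILES vector back to a string
#'
#' Inverse of \code{\link{encode_smiles}} on strings of length at most
#' \code{max_len} whose characters are all in the vocabulary: trailing
#' padding zeros are dropped and codes map back to tokens.
#'
#' @param codes integer vector from \code{\link{encode_smiles}}.
#' @param vocab the vocabulary used to encode.
#' @return a SMILES string.
#' @export
decode_smiles <- function(codes, vocab) {
  codes <- codes[codes != 0L]
  tokens <- names(vocab)[match(codes, unname(vocab))]
  if (anyNA(tokens)) stop("code not in vocabulary")
  paste(tokens, collapse = "")
}

#' Encode a list of SMILES strings into a matrix
#'
#' @param smiles_list character vector, one SMILES per drug.
#' @param vocab vocabulary; built from \code{smiles_list} when omitted.
#' @param max_len output width (default 85).
#' @return n x max_len integer matrix.
#' @export
encode_smiles_matrix <- function(smiles_list, vocab = NULL, max_len = 85L) {
  if (is.null(vocab)) vocab <- build_vocabulary(smiles_list)
  out <- t(vapply(smiles_list, encode_smiles, integer(max_len),
                  vocab = vocab, max_len = max_len))
  rownames(out) <- names(smiles_list)
  out
}

#' Write a vocabulary as a two-column table
#'
#' @param vocab a \code{smiles_vocabulary}.
#' @param path output path (TSV: token, code).
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(
    data.frame(token = names(vocab), code = unname(unclass(vocab))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a vocabulary written by \code{write_vocabulary}
#' @param path input path.
#' @return a \code{smiles_vocabulary}.
#' @export
read_vocabulary <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer"),
                           quote = "", comment.char = "")
  vocab <- tab$code
  names(vocab) <- tab$token
  class(vocab) <- "smiles_vocabulary"
  vocab
}

#' Stack a drug block over a miRNA block with front zero-padding
#'
#' The two blocks usually differ in width; the narrower one gains leading
#' (prepended) zero columns until both have width \code{max(a, b)}, then
#' drug rows are stacked above miRNA rows. With the full-scale widths,
#' stacking 920-column fingerprints over 172-column expression profiles
#' prepends 748 zero columns to the expression block. Padding never changes
#' the Frobenius norm of either block.
#'
#' @param drug_block p x a numeric matrix.
#' @param mirna_block q x b numeric matrix.
#' @param modal_index which of the four modal combinations this input
#'   represents (1..4); stored for bookkeeping.
#' @return a \code{modal_input}: list with \code{X} ((p+q) x max(a,b)),
#'   \code{d_u}, \code{p}, \code{q}, \code{modal_index}.
#' @export
pad_and_stack <- function(drug_block, mirna_block, modal_index = NA_integer_) {
  drug_block <- as.matrix(drug_block)
  mirna_block <- as.matrix(mirna_block)
  a <- ncol(drug_block); b <- ncol(mirna_block)
  d_u <- max(a, b)
  pad_front <- function(m, width) {
    if (ncol(m) == width) return(m)
    cbind(matrix(0, nrow(m), width - ncol(m)), m)
  }
  X <- rbind(pad_front(drug_block, d_u), pad_front(mirna_block, d_u))
  dimnames(X) <- NULL
  structure(list(modal_index = modal_index, X = X, d_u = d_u,
                 p = nrow(drug_block), q = nrow(mirna_block)),
            class = "modal_input")
}

#' Assemble the four modal input matrices
#'
#' The four views pair each drug feature with each miRNA feature:
#' modal 1 = fingerprint + expression, modal 2 = fingerprint + GO
#' similarity, modal 3 = SMILES encoding + expression, modal 4 = SMILES
#' encoding + GO similarity. Each pair is front-padded to a common width
#' and stacked drugs-first via \code{\link{pad_and_stack}}.
#'
#' @param fs a fully imputed \code{\link{feature_set}}.
#' @return list of four \code{modal_input} objects.
#' @export
build_modal_inputs <- function(fs) {
  if (anyNA(fs$X_m1) || anyNA(fs$X_m2))
    stop("feature set contains missing values; impute first")
  list(pad_and_stack(fs$X_d1, fs$X_m1, 1L),
       pad_and_stack(fs$X_d1, fs$X_m2, 2L),
       pad_and_stack(fs$X_d2, fs$X_m1, 3L),
       pad_and_stack(fs$X_d2, fs$X_m2, 4L))
}
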