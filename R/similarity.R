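# Drug-similarity matrix construction: Jaccard similarity from binary
# drug-feature matrices and Gaussian Interaction Profile (GIP) similarity
# from the DDI label matrix.

#' Jaccard similarity between two binary feature vectors
#'
#' Computes \eqn{J(u_a, u_b) = M_{11} / (M_{01} + M_{10} + M_{11})}, where
#' \eqn{M_{11}} counts positions set in both vectors and \eqn{M_{01}},
#' \eqn{M_{10}} positions set in exactly one. When both vectors are all-zero
#' the denominator vanishes and 0 is returned by convention.
#'
#' @param u_a,u_b Binary (0/1) vectors of equal length.
#' @return A similarity in \code{[0, 1]}.
#' @examples
#' jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)) # 1/3
#' @export
jaccard_similarity <- function(u_a, u_b) {
  if (length(u_a) != length(u_b))
    stop("feature vectors have different lengths (", length(u_a), " vs ",
         length(u_b), ")", call. = FALSE)
  if (!is_binary(u_a) || !is_binary(u_b))
    stop("feature vectors must contain only 0/1 entries", call. = FALSE)
  m11 <- sum(u_a == 1 & u_b == 1)
  denom <- sum(u_a == 1 | u_b == 1) # = M01 + M10 + M11
  if (denom == 0) return(0)
  m11 / denom
}

#' Build a Jaccard similarity matrix from a binary drug-feature matrix
#'
#' Each drug is a row of indicators over \code{M} features (targets, side
#' effects, pathways, ...). Entry \code{(i, j)} of the result is the Jaccard
#' score of rows \code{i} and \code{j}. The diagonal is 1, including for
#' all-zero rows (identical-vector convention), which keeps the output a
#' valid similarity matrix with unit diagonal.
#'
#' @param features N x M matrix with entries in \{0, 1\}; rownames are used
#'   as drug identifiers (generated when absent).
#' @param modality Optional text label for the modality.
#' @return N x N symmetric numeric matrix with drug ids as dimnames and the
#'   modality label in \code{attr(, "modality")}.
#' @export
build_jaccard_matrix <- function(features, modality = "jaccard") {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop("need at least 2 drugs to build a similarity matrix", call. = FALSE)
  if (ncol(features) < 1L) stop("need at least 1 feature", call. = FALSE)
  if (!is_binary(features))
    stop("feature matrix must contain only 0/1 entries", call. = FALSE)
  ids <- rownames(features) %||% paste0("drug", seq_len(nrow(features)))
  if (anyDuplicated(ids)) stop("drug ids must be unique", call. = FALSE)
  storage.mode(features) <- "double"
  m11 <- tcrossprod(features)               # co-occurring features
  r <- rowSums(features)
  denom <- outer(r, r, "+") - m11           # |union| = r_i + r_j - M11
  S <- ifelse(denom > 0, m11 / denom, 0)
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  attr(S, "modality") <- modality
  S
}

#' Gaussian Interaction Profile (GIP) similarity from a DDI label matrix
#'
#' Treats each drug's row of the binary interaction-label matrix as its
#' interaction profile \eqn{y_a} and computes the Gaussian kernel
#' \eqn{GIP(a, b) = \exp(-\gamma_g \|y_a - y_b\|^2)} with the bandwidth
#' normalised by the mean squared profile norm,
#' \eqn{\gamma_g = s / (\frac{1}{N}\sum_a \|y_a\|^2)} for scale \code{s}.
#' Drugs with resembling known interactions thereby receive high similarity.
#' With no positive labels at all the normaliser is zero and the identity
#' matrix is returned.
#'
#' @param labels N x N symmetric binary matrix of known interactions
#'   (diagonal ignored).
#' @param bandwidth_scale Positive multiplier on the normalised bandwidth.
#' @return N x N similarity matrix in \code{[0, 1]} with unit diagonal.
#' @export
build_gip_matrix <- function(labels, bandwidth_scale = 1) {
  labels <- validate_label_matrix(labels)
  if (bandwidth_scale <= 0) stop("bandwidth_scale must be positive", call. = FALSE)
  ids <- rownames(labels)
  n <- nrow(labels)
  r <- rowSums(labels)                      # ||y_a||^2 for binary rows
  norm <- mean(r)
  if (norm == 0) {
    S <- diag(n)
    dimnames(S) <- list(ids, ids)
    attr(S, "modality") <- "GIP"
    return(S)
  }
  g <- bandwidth_scale / norm
  d2 <- outer(r, r, "+") - 2 * tcrossprod(labels)  # ||y_a - y_b||^2
  S <- exp(-g * pmax(d2, 0))
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  attr(S, "modality") <- "GIP"
  S
}

#' Validate (and lightly repair) a DDI label matrix
#'
#' Checks binary entries, symmetrises by logical OR with a warning when the
#' input is asymmetric, and zeroes the diagonal (self-interactions are
#' ignored).
#'
#' @param labels Square binary matrix.
#' @return The validated N x N 0/1 matrix with drug-id dimnames.
#' @export
validate_label_matrix <- function(labels) {
  labels <- as.matrix(labels)
  if (nrow(labels) != ncol(labels))
    stop("label matrix must be square", call. = FALSE)
  if (anyNA(labels) || !is_binary(labels))
    stop("label matrix must contain only 0/1 entries", call. = FALSE)
  storage.mode(labels) <- "double"
  if (!isTRUE(all.equal(labels, t(labels), tolerance = 0))) {
    warning("label matrix is asymmetric; symmetrising by logical OR")
    labels <- pmax(labels, t(labels))
  }
  diag(labels) <- 0
  ids <- rownames(labels) %||% paste0("drug", seq_len(nrow(labels)))
  if (anyDuplicated(ids)) stop("drug ids must be unique", call. = FALSE)
  dimnames(labels) <- list(ids, ids)
  labels
}

# Validate an N x N similarity matrix: symmetric within tol, entries in [0,1].
assert_similarity_matrix <- function(S, tol = 1e-9, name = "similarity matrix") {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop(name, " must be a square matrix", call. = FALSE)
  if (anyNA(S)) stop(name, " contains missing values", call. = FALSE)
  if (max(abs(S - t(S))) > tol)
    stop(name, " is not symmetric (tolerance ", tol, ")", call. = FALSE)
  if (min(S) < -tol || max(S) > 1 + tol)
    stop(name, " has entries outside [0, 1]", call. = FALSE)
  invisible(S)
}

#' Read / write similarity matrices as TSV
#'
#' The on-disk format is a tab-separated table whose first row and first
#' column carry the drug identifiers. \code{read_similarity_tsv} validates
#' symmetry and the \code{[0, 1]} range; a write/read round trip preserves
#' values to better than 1e-12.
#'
#' @param path File path.
#' @param m Similarity matrix as returned by the builders.
#' @return \code{read_similarity_tsv} returns the validated matrix.
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  if (anyNA(m)) stop("missing/NaN entries in ", path, call. = FALSE)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("row and column drug ids disagree in ", path, call. = FALSE)
  assert_similarity_matrix(m)
  m
}

#' @rdname read_similarity_tsv
#' @export
write_similarity_tsv <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  df <- data.frame(drug_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
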