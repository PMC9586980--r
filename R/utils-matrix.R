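# Half-vectorization helpers. The package-wide convention for vech ordering is
# the lower triangle taken column-major: (1,1),(2,1),...,(k,1),(2,2),(3,2),...
# When a matrix is expanded with a gene, the gene occupies row/column 1
# ("gene-first"), so its variance is the first vech element.

#' Half-vectorize a symmetric matrix
#'
#' Stacks the lower triangle of `M` column-major (diagonal included).
#'
#' @param M Square symmetric matrix.
#' @return Numeric vector of length `k(k+1)/2`.
#' @export
vech <- function(M) {
  M[lower.tri(M, diag = TRUE)]
}

#' Rebuild a symmetric matrix from its half-vectorization
#'
#' @param v Numeric vector of length `k(k+1)/2`.
#' @param labels Optional row/column names.
#' @return Symmetric `k x k` matrix.
#' @export
unvech <- function(v, labels = NULL) {
  k <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(k - round(k)) > 1e-8)
    stop("length of 'v' is not a triangular number")
  k <- round(k)
  M <- matrix(0, k, k)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M) - diag(diag(M), k)
  if (!is.null(labels)) dimnames(M) <- list(labels, labels)
  M
}

# Position of element (i, j) of a k x k symmetric matrix inside vech().
vech_index <- function(i, j, k) {
  ii <- pmax(i, j)
  jj <- pmin(i, j)
  (jj - 1) * k - (jj - 1) * jj / 2 + ii
}

# Index pairs (i, j) corresponding to each vech position, k x (k+1)/2 rows.
vech_pairs <- function(k) {
  j <- rep(seq_len(k), times = k:1)
  i <- unlist(lapply(seq_len(k), function(col) col:k))
  cbind(i = i, j = j)
}

force_symmetric <- function(M) (M + t(M)) / 2
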