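#' Smooth a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue clipping: eigenvalues below a small floor are raised to the
#' floor and the matrix is reconstructed. Genetic covariance and sampling
#' covariance matrices estimated from finite GWAS samples are occasionally
#' indefinite; downstream weighted least squares requires (at least) positive
#' semi-definite input, so indefinite matrices are smoothed before fitting.
#'
#' When standard errors are supplied (as `V_for_check`, the sampling
#' covariance of `vech(M)`), the largest absolute pre/post change expressed in
#' Z-statistic units, `max |pre - post| / SE`, is reported; a discrepancy
#' above 1.96 indicates the smoothing materially moved a point estimate and a
#' warning is raised for the caller to handle.
#'
#' @param M Square symmetric matrix.
#' @param V_for_check Optional sampling covariance matrix of `vech(M)` used to
#'   express the smoothing-induced changes as Z-statistic discrepancies.
#' @param floor Eigenvalue floor; eigenvalues below it are clipped up to it.
#' @return The smoothed matrix, with attributes `smoothed` (logical) and
#'   `max_z_discrepancy` (numeric, `NA` when no SEs supplied).
#' @export
smooth_nearest_psd <- function(M, V_for_check = NULL, floor = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop("'M' must be a square matrix")
  M <- force_symmetric(M)
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= floor) {
    attr(M, "smoothed") <- FALSE
    attr(M, "max_z_discrepancy") <- if (is.null(V_for_check)) NA_real_ else 0
    return(M)
  }
  vals <- pmax(e$values, floor)
  out <- force_symmetric(e$vectors %*% (vals * t(e$vectors)))
  dimnames(out) <- dimnames(M)
  maxz <- NA_real_
  if (!is.null(V_for_check)) {
    se <- sqrt(pmax(diag(V_for_check), .Machine$double.eps))
    z <- abs(vech(out) - vech(M)) / se
    maxz <- max(z)
    if (maxz > 1.96)
      warning(sprintf(
        "smoothing moved a point estimate by %.2f SEs (> 1.96)", maxz))
  }
  attr(out, "smoothed") <- TRUE
  attr(out, "max_z_discrepancy") <- maxz
  out
}
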