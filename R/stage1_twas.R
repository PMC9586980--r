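# Stage 1: summary-based TWAS (weighted Z combination), rescaling of TWAS
# Z-statistics into gene-phenotype covariances, and assembly of the
# gene-expanded matrices used as Stage-2 input.

#' Summary-based TWAS Z-statistic
#'
#' Combines GWAS Z-statistics with per-SNP functional weights:
#' `Z = (w' z) / sqrt(w' R w)`, where `R` is the reference SNP correlation
#' matrix restricted to the weight SNPs. A ridge of `1e-3` is added to the
#' diagonal of `R` before the quadratic form. Weight alleles are aligned to
#' the summary statistics (weight sign flipped when a1/a2 are swapped).
#' Genes with more than `max_missing` of their weight SNPs absent from the
#' summary statistics are skipped (returns `NA` with attribute
#' `skipped = TRUE`); missing-SNP imputation is not performed.
#'
#' @param weights A `tsem_weights` object (see [eqtl_weights()]).
#' @param sumstats Summary-statistics `data.frame` for one trait.
#' @param ld_reference SNP correlation matrix with snp ids as dimnames.
#' @param ridge Diagonal regularization added to `ld_reference`.
#' @param max_missing Maximum tolerated fraction of missing weight SNPs.
#' @return The TWAS Z-statistic (scalar).
#' @export
twas_z <- function(weights, sumstats, ld_reference, ridge = 1e-3,
                   max_missing = 0.5) {
  wt <- weights$weights
  m <- match(wt$snp_id, sumstats$snp_id)
  frac_missing <- mean(is.na(m))
  if (frac_missing > max_missing) {
    out <- NA_real_
    attr(out, "skipped") <- TRUE
    return(out)
  }
  wt <- wt[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  z <- sumstats$z[m]
  w <- wt$weight
  # align weight effect alleles to the sumstats orientation
  sa1 <- toupper(sumstats$a1[m]); sa2 <- toupper(sumstats$a2[m])
  wa1 <- toupper(wt$a1); wa2 <- toupper(wt$a2)
  swap <- wa1 == sa2 & wa2 == sa1
  bad <- !(swap | (wa1 == sa1 & wa2 == sa2))
  if (any(bad)) stop("weight SNP alleles incompatible with sumstats")
  w[swap] <- -w[swap]
  ri <- match(wt$snp_id, rownames(ld_reference))
  if (anyNA(ri)) stop("weight SNPs missing from the LD reference matrix")
  R <- ld_reference[ri, ri, drop = FALSE] + ridge * diag(length(ri))
  denom <- as.numeric(t(w) %*% R %*% w)
  if (denom <= 0) stop("w' R w is nonpositive; TWAS Z undefined")
  as.numeric(crossprod(w, z)) / sqrt(denom)
}

#' Rescale a TWAS Z-statistic for a continuous trait
#'
#' Converts a TWAS Z into a partially standardized regression coefficient
#' `b = Z / sqrt(N sigma2_gene)` with `SE = 1 / sqrt(N sigma2_gene)` (the
#' coefficient is standardized with respect to the phenotype but not the
#' gene) and the gene-phenotype covariance `cov = b * sigma2_gene`.
#'
#' @param z TWAS Z-statistic.
#' @param n GWAS sample size.
#' @param sigma2_gene Cis-heritability of the gene's expression.
#' @return Named vector `c(b, se, cov)`.
#' @export
scale_continuous <- function(z, n, sigma2_gene) {
  if (n <= 0 || sigma2_gene <= 0) stop("n and sigma2_gene must be positive")
  se <- 1 / sqrt(n * sigma2_gene)
  b <- z * se
  c(b = b, se = se, cov = b * sigma2_gene)
}

#' Rescale a TWAS Z-statistic for a binary trait
#'
#' Backs a logit-scale coefficient out of the Z-statistic using the summed
#' effective sample size, `b* = Z / sqrt((Neff/4) sigma2_gene)` with
#' `SE* = 1 / sqrt((Neff/4) sigma2_gene)`, then partially standardizes both
#' by `sqrt(sigma2_gene b*^2 + pi^2/3)` (the logistic residual variance).
#'
#' @param z TWAS Z-statistic.
#' @param n_eff Sum of effective sample sizes across contributing cohorts.
#' @param sigma2_gene Cis-heritability of the gene's expression.
#' @return Named vector `c(b, se, cov)`.
#' @export
scale_binary <- function(z, n_eff, sigma2_gene) {
  if (n_eff <= 0 || sigma2_gene <= 0)
    stop("n_eff and sigma2_gene must be positive")
  se_star <- 1 / sqrt((n_eff / 4) * sigma2_gene)
  b_star <- z * se_star
  denom <- sqrt(sigma2_gene * b_star^2 + pi^2 / 3)
  b <- b_star / denom
  c(b = b, se = se_star / denom, cov = b * sigma2_gene)
}

#' Expand LDSC matrices with one gene's TWAS estimates
#'
#' Builds the gene-expanded covariance matrix (gene first): the gene's
#' cis-heritability occupies cell (1,1), the gene-phenotype covariances
#' fill column 1, and the LDSC genetic covariance block fills the rest. The
#' matching sampling covariance matrix has three blocks: the gene block,
#' whose diagonal holds the squared gene-phenotype SEs on the covariance
#' scale (`se_cov = se * sigma2_gene`) and whose off-diagonals are
#' `intercept_ij * se_cov_i * se_cov_j` (cross-trait LDSC intercepts are
#' sampling correlations and are rescaled to covariances); the LDSC block
#' copied from `est$V`; and a zero cross-block, since the sampling error of
#' a single gene's effect is independent of genome-wide LDSC estimates. The
#' sampling variance of the gene's own variance is treated as fixed at
#' `sigma2_gene_var` (1e-4), with zero covariance with everything else.
#'
#' @param est A `tsem_ldsc` object.
#' @param cov_gene Per-trait gene-phenotype covariances (ordered as
#'   `est$traits`).
#' @param se_gene Per-trait SEs of the partially standardized coefficients
#'   (the `se` element of [scale_continuous()] / [scale_binary()]).
#' @param sigma2_gene Cis-heritability of the gene's expression.
#' @param gene_id,tissue Labels carried through to results.
#' @param sigma2_gene_var Fixed sampling variance for `sigma2_gene`.
#' @return Object of class `tsem_gene_matrices` with elements `S`
#'   ((k+1) x (k+1)), `V`, `traits`, `gene_id`, `tissue`, `sigma2_gene`.
#' @export
assemble_full_matrices <- function(est, cov_gene, se_gene, sigma2_gene,
                                   gene_id = "gene", tissue = "panel",
                                   sigma2_gene_var = 1e-4) {
  k <- nrow(est$S)
  if (length(cov_gene) != k || length(se_gene) != k)
    stop("cov_gene / se_gene length does not match the trait count")
  traits <- est$traits
  lab <- c("gene", traits)
  kk <- k + 1

  S_full <- matrix(0, kk, kk, dimnames = list(lab, lab))
  S_full[1, 1] <- sigma2_gene
  S_full[2:kk, 1] <- S_full[1, 2:kk] <- cov_gene
  S_full[2:kk, 2:kk] <- est$S

  p_full <- kk * (kk + 1) / 2
  V_full <- matrix(0, p_full, p_full)
  se_cov <- se_gene * sigma2_gene

  idx_gene_var <- vech_index(1, 1, kk)
  V_full[idx_gene_var, idx_gene_var] <- sigma2_gene_var
  idx_gene <- vech_index(seq_len(k) + 1, 1, kk)
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      v <- if (i == j) se_cov[i]^2 else est$I[i, j] * se_cov[i] * se_cov[j]
      V_full[idx_gene[i], idx_gene[j]] <- v
      V_full[idx_gene[j], idx_gene[i]] <- v
    }
  }
  pairs_k <- vech_pairs(k)
  idx_ldsc <- vech_index(pairs_k[, "i"] + 1, pairs_k[, "j"] + 1, kk)
  V_full[idx_ldsc, idx_ldsc] <- est$V

  structure(list(S = S_full, V = V_full, traits = traits,
                 gene_id = gene_id, tissue = tissue,
                 sigma2_gene = sigma2_gene),
            class = "tsem_gene_matrices")
}

#' Convert between the top1 functional weight and the eQTL effect
#'
#' The single-best-eQTL ("top1") weight stored by weight-training pipelines
#' relates to the partially standardized eQTL effect as
#' `b_eqtl = top1 / (sigma_snp * sqrt(n - 1))`, where `sigma_snp` is the SNP
#' standard deviation in the LD reference and `n` the weight-training
#' sample size.
#'
#' @param top1 Stored top1 weight.
#' @param sigma_snp SNP standard deviation.
#' @param n Weight-training sample size.
#' @return The implied `b_eqtl` (or `top1` for the inverse).
#' @export
beqtl_from_top1 <- function(top1, sigma_snp, n) {
  top1 / (sigma_snp * sqrt(n - 1))
}

#' @rdname beqtl_from_top1
#' @param b_eqtl Partially standardized eQTL effect.
#' @export
top1_from_beqtl <- function(b_eqtl, sigma_snp, n) {
  b_eqtl * sigma_snp * sqrt(n - 1)
}
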