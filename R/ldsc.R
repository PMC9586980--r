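# Multivariable LD score regression: genetic covariance matrix S, its
# block-jackknife sampling covariance V, and the intercept matrix I from
# munged GWAS summary statistics.

#' Multivariable LD score regression
#'
#' For every trait pair (i, j) the per-SNP product of Z-statistics is
#' regressed on `sqrt(Ni * Nj) * l2 / M` with a free intercept; the slope is
#' the genetic covariance (SNP heritability when i = j) and the intercept
#' is the (cross-trait) LDSC intercept. Heteroscedasticity weights
#' `1 / ((1 + Ni h2i l/M)(1 + Nj h2j l/M))` are updated once from a
#' first-pass unweighted fit. The sampling covariance `V` of all
#' nonredundant S elements (vech order, lower triangle column-major) is
#' estimated by a delete-one block jackknife over `n_blocks` contiguous SNP
#' blocks, so that its off-diagonals capture dependencies between the
#' sampling errors of different S elements (e.g. under sample overlap).
#'
#' @param sumstats List of munged summary-statistics data.frames, one per
#'   trait, named by trait. All are restricted to SNPs present in `ld`.
#' @param ld LD score table (`snp_id`, `l2`, attribute `M`); see
#'   [read_ld_scores()].
#' @param n_blocks Number of contiguous jackknife blocks (default 200).
#' @return Object of class `tsem_ldsc` with elements `traits`, `S` (k x k),
#'   `V` (p* x p* with p* = k(k+1)/2), `I` (intercept matrix), `m_snps`,
#'   `n_blocks`, `N` (mean per-trait sample sizes).
#' @export
ldsc_covariance <- function(sumstats, ld, n_blocks = 200) {
  k <- length(sumstats)
  traits <- names(sumstats)
  if (is.null(traits)) traits <- paste0("trait", seq_len(k))
  common <- Reduce(intersect, c(lapply(sumstats, `[[`, "snp_id"),
                                list(ld$snp_id)))
  if (length(common) < n_blocks)
    stop("fewer SNPs than jackknife blocks")
  ldm <- match(common, ld$snp_id)
  l2 <- ld$l2[ldm]
  M <- attr(ld, "M")
  if (is.null(M)) M <- nrow(ld)
  Z <- matrix(NA_real_, length(common), k)
  N <- matrix(NA_real_, length(common), k)
  for (t in seq_len(k)) {
    m <- match(common, sumstats[[t]]$snp_id)
    Z[, t] <- sumstats[[t]]$z[m]
    N[, t] <- sumstats[[t]]$n[m]
  }
  est <- ldsc_core(Z, N, l2, M, n_blocks)
  est$traits <- traits
  dimnames(est$S) <- list(traits, traits)
  dimnames(est$I) <- list(traits, traits)
  est
}

# Core regression machinery on matrices; Z and N are m x k, l2 length m.
# Exposed for the simulation pipeline, which generates Z directly.
ldsc_core <- function(Z, N, l2, M, n_blocks = 200) {
  m <- nrow(Z); k <- ncol(Z)
  if (stats::var(l2) == 0)
    stop("LD scores have zero variance; regression is singular")
  if (n_blocks < 2 || n_blocks > m) stop("invalid number of blocks")
  pairs <- vech_pairs(k)
  p_star <- nrow(pairs)
  block <- ceiling(seq_len(m) / (m / n_blocks))
  block[block > n_blocks] <- n_blocks

  # first pass: unweighted slopes for the weight update
  h2_first <- numeric(k)
  Nbar <- colMeans(N)
  for (t in seq_len(k)) {
    x <- N[, t] * l2 / M
    y <- Z[, t]^2
    cf <- stats::lm.fit(cbind(1, x), y)$coefficients
    h2_first[t] <- max(cf[2], 0)
  }
  wt_term <- function(t) 1 + Nbar[t] * h2_first[t] * l2 / M

  slopes <- numeric(p_star)
  icpt <- numeric(p_star)
  jk <- matrix(0, n_blocks, p_star)
  for (p in seq_len(p_star)) {
    i <- pairs[p, "i"]; j <- pairs[p, "j"]
    x <- sqrt(N[, i] * N[, j]) * l2 / M
    y <- Z[, i] * Z[, j]
    w <- 1 / (wt_term(i) * wt_term(j))
    # weighted crossproducts, accumulated per jackknife block
    sw  <- rowsum(w, block);        swx  <- rowsum(w * x, block)
    swx2 <- rowsum(w * x * x, block); swy <- rowsum(w * y, block)
    swxy <- rowsum(w * x * y, block)
    Tw <- sum(sw); Twx <- sum(swx); Twx2 <- sum(swx2)
    Twy <- sum(swy); Twxy <- sum(swxy)
    det_full <- Tw * Twx2 - Twx^2
    slopes[p] <- (Tw * Twxy - Twx * Twy) / det_full
    icpt[p] <- (Twx2 * Twy - Twx * Twxy) / det_full
    dTw <- Tw - sw; dTwx <- Twx - swx; dTwx2 <- Twx2 - swx2
    dTwy <- Twy - swy; dTwxy <- Twxy - swxy
    jk[, p] <- (dTw * dTwxy - dTwx * dTwy) / (dTw * dTwx2 - dTwx^2)
  }
  V <- stats::cov(jk) * (n_blocks - 1)^2 / n_blocks
  S <- unvech(slopes)
  I <- unvech(icpt)
  structure(list(traits = paste0("trait", seq_len(k)), S = S,
                 V = force_symmetric(V), I = I, m_snps = m, M = M,
                 n_blocks = n_blocks, N = Nbar),
            class = "tsem_ldsc")
}

#' Convert heritabilities of binary traits to the liability scale
#'
#' Applies the standard observed-scale to liability-scale conversion
#' factor `K^2 (1-K)^2 / (P (1-P) phi(z)^2)`, where `K` is the population
#' prevalence, `P` the sample prevalence and `phi(z)` the standard-normal
#' density at the threshold `z = qnorm(1 - K)`. Heritabilities scale by the
#' factor, covariances involving one binary trait by its square root, and
#' the sampling covariance entries by the product of the per-trait factors
#' (bilinearity). Continuous traits (`NA` prevalence) are untouched. For
#' GWAS reported on effective sample sizes, supply a sample prevalence of
#' 0.5 with the summed effective N.
#'
#' @param est A `tsem_ldsc` object.
#' @param sample_prev,pop_prev Numeric vectors (length k) of sample and
#'   population prevalences; `NA` marks a continuous trait.
#' @return The rescaled `tsem_ldsc` object.
#' @export
liability_convert <- function(est, sample_prev, pop_prev) {
  k <- nrow(est$S)
  stopifnot(length(sample_prev) == k, length(pop_prev) == k)
  binary <- !is.na(sample_prev) & !is.na(pop_prev)
  if (any(sample_prev[binary] <= 0 | sample_prev[binary] >= 1 |
          pop_prev[binary] <= 0 | pop_prev[binary] >= 1))
    stop("prevalences must lie strictly within (0, 1)")
  s <- rep(1, k)
  if (any(binary)) {
    K <- pop_prev[binary]; P <- sample_prev[binary]
    z <- stats::qnorm(1 - K)
    fac <- K^2 * (1 - K)^2 / (P * (1 - P) * stats::dnorm(z)^2)
    s[binary] <- sqrt(fac)
  }
  est$S <- est$S * (s %o% s)
  pairs <- vech_pairs(k)
  f <- s[pairs[, "i"]] * s[pairs[, "j"]]
  est$V <- est$V * (f %o% f)
  est
}

#' @export
print.tsem_ldsc <- function(x, ...) {
  cat(sprintf("Multivariable LDSC estimate: %d traits, %d SNPs, %d blocks\n",
              nrow(x$S), x$m_snps, x$n_blocks))
  cat("S (genetic covariance):\n"); print(round(x$S, 4))
  cat("Intercepts:\n"); print(round(x$I, 4))
  invisible(x)
}
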