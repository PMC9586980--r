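# Genome-wide validation simulator: GWAS Z-statistics are generated from
# the LD score regression sampling model, a focal eQTL injects gene
# expression signal through the eQTL -> factor -> trait chain, and both the
# T-SEM pipeline and an ad hoc factor-TWAS pipeline are run per replicate.

#' Configuration for the SNP-level simulations
#'
#' Defaults are the study conditions of the validation design: five
#' continuous traits, 20\% heritable, genetically (and phenotypically)
#' correlated at 0.7, GWAS n of 150,000 each with no sample overlap,
#' univariate intercept 1.04; the focal eQTL has SNP standard deviation
#' 0.706 in the LD reference, a weight-training sample of n = 144, an eQTL
#' effect of 0.442 on expression, a gene effect of -0.089 on the factor,
#' and equal unstandardized loadings `sqrt(rg * h2) = 0.374`. `m` defaults
#' to a desk-scale 100,000 synthetic LD-score SNPs (the full-scale design
#' uses 1,184,461).
#'
#' @param k Number of traits.
#' @param h2 Per-trait SNP heritability.
#' @param rg Pairwise genetic correlation.
#' @param n Per-trait GWAS sample size.
#' @param n_overlap Overlapping individuals across GWAS pairs.
#' @param rho Phenotypic correlation (only matters with overlap).
#' @param intercept Univariate LDSC intercept (1 + a).
#' @param m Number of LD-score SNPs.
#' @param sigma_snp Focal SNP standard deviation in the LD reference.
#' @param n_train Weight-training sample size for the focal gene.
#' @param b_eqtl Population eQTL effect (expression-standardized).
#' @param gamma Gene effect on the common factor.
#' @param lambda Factor loadings; default `sqrt(rg * h2)` for all traits.
#' @param scenario Scenario 1..5 (see [focal_effects()]).
#' @param reps Number of simulation replicates.
#' @param vary_beqtl Draw a population eQTL effect per replicate from its
#'   sampling distribution while keeping the functional weight fixed.
#' @param n_tests Bonferroni denominator (default 52849).
#' @param n_blocks LDSC jackknife blocks.
#' @param seed Base seed.
#' @return List of class `snp_sim_config`.
#' @export
snp_sim_config <- function(k = 5, h2 = 0.2, rg = 0.7, n = 150000,
                           n_overlap = 0, rho = 0.7, intercept = 1.04,
                           m = 100000, sigma_snp = 0.706, n_train = 144,
                           b_eqtl = 0.442, gamma = -0.089,
                           lambda = rep(sqrt(rg * h2), k),
                           scenario = 1, reps = 50, vary_beqtl = FALSE,
                           n_tests = 52849, n_blocks = 200, seed = 1) {
  stopifnot(h2 >= 0, m >= n_blocks, scenario %in% 1:5, length(lambda) == k)
  structure(list(k = k, h2 = h2, rg = rg, n = n, n_overlap = n_overlap,
                 rho = rho, intercept = intercept, m = m,
                 sigma_snp = sigma_snp, n_train = n_train, b_eqtl = b_eqtl,
                 gamma = gamma, lambda = lambda, scenario = scenario,
                 reps = reps, vary_beqtl = vary_beqtl, n_tests = n_tests,
                 n_blocks = n_blocks, seed = seed),
            class = "snp_sim_config")
}

#' Generate genome-wide GWAS Z-statistics from the LDSC sampling model
#'
#' For SNP j the k-vector of Z-statistics is multivariate normal with mean
#' zero and covariance `N h2 l(j)/M + 1 + a` on the diagonal and
#' `sqrt(Ni Nj) sigma_g l(j)/M + rho Ns/sqrt(Ni Nj)` off the diagonal.
#' The covariance is `C0 + l(j) C1` with fixed matrices C0 (intercepts)
#' and C1 (scaled genetic covariance), so draws are formed exactly as
#' `Z_j = L0' u_j + sqrt(l(j)) L1' v_j` with independent standard normal
#' u, v and Cholesky factors of C0 and C1.
#'
#' @param cfg A [snp_sim_config()].
#' @param ld LD score table (defaults to a synthetic one of size `cfg$m`).
#' @param S_g Optional genetic covariance matrix overriding the equal
#'   h2/rg structure.
#' @return List with `Z` (m x k matrix), `ld`, and `sumstats` — a list of
#'   k summary-statistics data.frames ready for [ldsc_covariance()].
#' @export
generate_gwas_z <- function(cfg, ld = NULL, S_g = NULL) {
  if (is.null(ld)) ld <- make_ld_scores(cfg$m, seed = cfg$seed)
  m <- nrow(ld)
  k <- cfg$k
  if (is.null(S_g)) {
    S_g <- matrix(cfg$rg * cfg$h2, k, k)
    diag(S_g) <- cfg$h2
  }
  Ns <- matrix(cfg$n_overlap, k, k); diag(Ns) <- 0
  C0 <- matrix(cfg$rho * Ns / cfg$n, k, k)
  diag(C0) <- cfg$intercept
  C1 <- cfg$n * S_g / attr(ld, "M")
  L0 <- chol(smooth_nearest_psd(C0, floor = 1e-10))
  L1 <- if (max(abs(C1)) == 0) matrix(0, k, k)
    else chol(smooth_nearest_psd(C1, floor = 0))
  U <- matrix(stats::rnorm(m * k), m, k)
  Vv <- matrix(stats::rnorm(m * k), m, k)
  Z <- U %*% L0 + (sqrt(ld$l2) * Vv) %*% L1
  sumstats <- lapply(seq_len(k), function(t)
    data.frame(snp_id = ld$snp_id, a1 = "A", a2 = "G", z = Z[, t],
               n = cfg$n, maf = 0.25, info = 1, stringsAsFactors = FALSE))
  names(sumstats) <- paste0("trait", seq_len(k))
  list(Z = Z, ld = ld, sumstats = sumstats)
}

#' Population and observed focal-SNP effects per scenario
#'
#' The population SNP effect on trait i is the product along the chain,
#' `b_GWAS,i = b_eqtl * gamma * lambda_i`, perturbed by scenario:
#' \enumerate{
#'   \item no perturbation (effects operate through the factor);
#'   \item sign reversed for three of the five traits;
#'   \item sign reversed and effect doubled for three of the five;
#'   \item set to 0 for three of the five;
#'   \item set to 0 for all traits.
#' }
#' Observed effects are drawn independently around the population values
#' with sampling variance `(1 - sigma2_snp b^2) / (sigma2_snp (n - 1))`
#' (zero cross-trait sampling covariance under zero sample overlap).
#'
#' @param cfg A [snp_sim_config()].
#' @param b_eqtl Population eQTL effect (defaults to `cfg$b_eqtl`;
#'   overridden per replicate when `vary_beqtl` is on).
#' @return List with `b_pop`, `b_obs`, `se`, `z` (each length k).
#' @export
focal_effects <- function(cfg, b_eqtl = cfg$b_eqtl) {
  k <- cfg$k
  b <- b_eqtl * cfg$gamma * cfg$lambda
  sub <- seq_len(min(3, k))
  b <- switch(cfg$scenario,
              b,
              { b[sub] <- -b[sub]; b },
              { b[sub] <- -2 * b[sub]; b },
              { b[sub] <- 0; b },
              rep(0, k))
  s2_snp <- cfg$sigma_snp^2
  v <- (1 - s2_snp * b^2) / (s2_snp * (cfg$n - 1))
  se <- sqrt(v)
  b_obs <- stats::rnorm(k, b, se)
  list(b_pop = b, b_obs = b_obs, se = se, z = b_obs / se)
}

#' Draw population eQTL effects from their sampling distribution
#'
#' `sigma2_beqtl = (1 - sigma2_snp b_eqtl^2) / (sigma2_snp (n - 1))`; draws
#' are normal around the point estimate. The functional weight used
#' downstream stays fixed, so each draw varies the degree of mismatch
#' between the population eQTL effect and the weight.
#'
#' @param cfg A [snp_sim_config()].
#' @param reps Number of draws.
#' @return Numeric vector of `b_eqtl` draws.
#' @export
sample_beqtl <- function(cfg, reps) {
  se <- sqrt(beqtl_sampling_variance(cfg$b_eqtl, cfg$sigma_snp, cfg$n_train))
  stats::rnorm(reps, cfg$b_eqtl, se)
}

#' @rdname sample_beqtl
#' @param b_eqtl,sigma_snp,n Effect, SNP standard deviation, training n.
#' @export
beqtl_sampling_variance <- function(b_eqtl, sigma_snp, n) {
  if (n <= 1) stop("n must exceed 1")
  (1 - sigma_snp^2 * b_eqtl^2) / (sigma_snp^2 * (n - 1))
}

#' Run the SNP-level simulation pipeline
#'
#' Per replicate: (a) genome-wide Z-statistics are generated and analysed
#' with multivariable LDSC to give (S, V, intercepts); (b) the T-SEM path
#' converts the focal SNP's trait Z-statistics (equal to the TWAS
#' Z-statistics under the single-SNP top1 weight) to gene-phenotype
#' covariances, expands the matrices, and fits the gene-on-factor model
#' plus Q_Gene; (c) the factor-TWAS path appends the focal SNP-phenotype
#' covariances to (S, V), estimates the SNP effect on the common factor,
#' and uses the resulting Z as the factor TWAS statistic. The focal SNP is
#' not part of the LD score panel, keeping the two generative layers
#' independent.
#'
#' @param cfg A [snp_sim_config()].
#' @param progress Print a dot per replicate.
#' @return One-row `data.frame` report (power at Bonferroni and nominal
#'   FPRs for T-SEM, factor TWAS, and Q_Gene; gamma summaries; failure
#'   count; T-SEM/factor-TWAS concordance), with per-rep records as
#'   attribute `reps`.
#' @export
run_snp_pipeline <- function(cfg, progress = FALSE) {
  k <- cfg$k
  bonf <- 0.05 / cfg$n_tests
  sigma2_gene <- cfg$b_eqtl^2 * cfg$sigma_snp^2  # expression variance tagged
  ld <- make_ld_scores(cfg$m, seed = cfg$seed)

  rec <- data.frame(rep = seq_len(cfg$reps), gamma = NA_real_,
                    gamma_p = NA_real_, q_p = NA_real_,
                    twasf_est = NA_real_, twasf_z = NA_real_,
                    twasf_p = NA_real_, b_eqtl = NA_real_)
  for (r in seq_len(cfg$reps)) {
    set.seed((cfg$seed * 10000L + cfg$scenario * 1000L + r) %%
               .Machine$integer.max)
    gen <- generate_gwas_z(cfg, ld = ld)
    est <- ldsc_core(gen$Z, matrix(cfg$n, cfg$m, k), ld$l2, attr(ld, "M"),
                     n_blocks = cfg$n_blocks)
    est$S <- smooth_nearest_psd(est$S, floor = 1e-6)
    est$V <- smooth_nearest_psd(est$V, floor = 1e-12)

    beq <- if (cfg$vary_beqtl) sample_beqtl(cfg, 1) else cfg$b_eqtl
    rec$b_eqtl[r] <- beq
    foc <- focal_effects(cfg, b_eqtl = beq)

    # T-SEM path: top1 weight => per-trait TWAS Z equals the focal SNP Z
    sc <- vapply(foc$z, function(z) scale_continuous(z, cfg$n, sigma2_gene),
                 numeric(3))
    mat <- assemble_full_matrices(est, cov_gene = sc["cov", ],
                                  se_gene = sc["se", ],
                                  sigma2_gene = sigma2_gene,
                                  gene_id = "focal", tissue = "sim")
    res <- tryCatch(fit_tsem(mat), error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$converged)) {
      rec$gamma[r] <- res$gamma_std
      rec$gamma_p[r] <- res$p
      rec$q_p[r] <- res$p_q
    }

    # factor-TWAS path: SNP appended as a predictor of the factor
    s2_snp <- cfg$sigma_snp^2
    mat_snp <- assemble_full_matrices(est, cov_gene = foc$b_obs * s2_snp,
                                      se_gene = foc$se,
                                      sigma2_gene = s2_snp,
                                      gene_id = "focal_snp", tissue = "sim")
    fsnp <- tryCatch(fit_gene_on_factor(mat_snp, "unit_loading"),
                     error = function(e) NULL)
    if (!is.null(fsnp) && isTRUE(fsnp$converged)) {
      # single-SNP top1 weight: the gene TWAS Z for the factor equals the
      # SNP's factor GWAS Z
      rec$twasf_est[r] <- fsnp$gamma_std_factor
      rec$twasf_z[r] <- fsnp$gamma_z
      rec$twasf_p[r] <- fsnp$gamma_p
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  ok <- !is.na(rec$gamma_p) & !is.na(rec$twasf_p)
  report <- data.frame(
    scenario = cfg$scenario, reps = cfg$reps,
    fit_failures = sum(!ok),
    power_tsem = 100 * mean(rec$gamma_p[ok] < bonf),
    power_twasfactor = 100 * mean(rec$twasf_p[ok] < bonf),
    power_q = 100 * mean(rec$q_p[ok] < bonf),
    fpr_tsem_05 = 100 * mean(rec$gamma_p[ok] < 0.05),
    fpr_twasfactor_05 = 100 * mean(rec$twasf_p[ok] < 0.05),
    fpr_q_05 = 100 * mean(rec$q_p[ok] < 0.05),
    mean_gamma = mean(rec$gamma[ok]), sd_gamma = stats::sd(rec$gamma[ok]),
    cor_tsem_twasf = stats::cor(rec$gamma[ok], rec$twasf_est[ok]))
  attr(report, "reps") <- rec
  attr(report, "seed") <- cfg$seed
  report
}
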