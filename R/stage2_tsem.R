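# Stage 2: the T-SEM models. A common factor is defined over the k traits,
# gene expression regresses the factor (g = gamma * x + e), and a two-step
# chi-square difference (Q_Gene) tests the null that the gene operates on
# the traits only through the factor.

.log_two_sided <- function(z) log(2) + stats::pnorm(-abs(z), log.p = TRUE)

.step1_syntax <- function(traits, identification, sigma2_gene,
                          equal_loadings = FALSE, anchor = traits[1]) {
  lam <- paste0("l_", traits)
  if (identification == "unit_loading") {
    if (equal_loadings) {
      terms <- paste0("1@", traits)    # all loadings scaled to unity
    } else {
      free <- setdiff(traits, anchor)
      terms <- c(paste0("1@", anchor), paste0("l_", free, "*", free))
    }
    extra <- "F ~~ e*F"
  } else {
    terms <- if (equal_loadings) paste0("l_eq*", traits)
      else paste0(lam, "*", traits)
    extra <- "F ~~ 1@F"
  }
  # the gene's variance is treated as known (its sampling variance is a
  # fixed nominal constant), so the parameter is fixed at the observed
  # value rather than freely estimated; this keeps all inference exactly
  # invariant to the chosen expression-variance metric
  paste(c(paste("F =~", paste(terms, collapse = " + ")),
          "F ~ gamma*gene",
          sprintf("gene ~~ %.15g@gene", sigma2_gene),
          extra,
          paste0(traits, " ~~ u_", traits, "*", traits)),
        collapse = "\n")
}

#' Fit the gene-on-factor T-SEM model
#'
#' Fits a single common factor over the k traits with gene expression
#' predicting the factor. Under `"unit_loading"` identification the first
#' trait's loading is fixed to 1 and the factor residual variance is free;
#' under `"unit_variance"` the factor residual variance is fixed to 1, so
#' the model-implied total factor variance is `1 + gamma^2 * sigma2_gene`.
#'
#' @param mat A `tsem_gene_matrices` object (see
#'   [assemble_full_matrices()]).
#' @param identification `"unit_loading"` or `"unit_variance"`.
#' @param equal_loadings Constrain all loadings equal (required for k = 2,
#'   where the unconstrained measurement model is not identified).
#' @param anchor Trait whose loading is fixed to 1 under unit-loading
#'   identification (the choice does not affect gamma's Z or Q_Gene).
#' @return A `tsem_fit` with extra fields: `gamma`, `gamma_se`, `gamma_p`
#'   (and `gamma_log_p`), `loadings`, `resid_traits`, `factor_var` (total),
#'   `var_explained` (share `gamma^2 s2 / (1 + gamma^2 s2)` of the factor
#'   variance attributable to the gene, unit-variance metric).
#' @export
fit_gene_on_factor <- function(mat,
                               identification = c("unit_loading",
                                                  "unit_variance"),
                               equal_loadings = FALSE,
                               anchor = mat$traits[1]) {
  identification <- match.arg(identification)
  traits <- mat$traits
  if (length(traits) < 2) stop("need at least two indicators")
  if (length(traits) == 2 && !equal_loadings)
    stop("two-indicator factors require equal_loadings = TRUE")
  s2 <- unname(mat$S["gene", "gene"])
  fit <- fit_dwls(mat$S, mat$V,
                  .step1_syntax(traits, identification, s2, equal_loadings,
                                anchor))
  est <- fit$estimates
  gamma <- est[["gamma"]]
  se <- fit$se[["gamma"]]
  # test statistic on the unit-variance-factor scale: gamma / sd(F_total)
  # is the same function of the fitted moments under every identification
  # (and anchor), so its delta-method Z is invariant, unlike the raw Wald Z
  expr <- if (identification == "unit_loading")
    "gamma / sqrt(e + gamma^2 * s2)" else "gamma / sqrt(1 + gamma^2 * s2)"
  gstd <- tryCatch(ghost_parameter(fit, expr, extra = list(s2 = s2)),
                   error = function(e) NULL)
  zstat <- if (!is.null(gstd) && gstd[["se"]] > 0)
    gstd[["value"]] / gstd[["se"]] else gamma / se
  lam <- numeric(length(traits)); names(lam) <- traits
  for (t in traits) {
    lab <- paste0("l_", t)
    lam[t] <- if (lab %in% names(est)) est[[lab]]
      else if ("l_eq" %in% names(est)) est[["l_eq"]] else 1
  }
  e_resid <- if (identification == "unit_loading") est[["e"]] else 1
  g2s2 <- (gamma * sqrt(s2) / sqrt(e_resid))^2  # scale-free gene share
  fit$gene_id <- mat$gene_id; fit$tissue <- mat$tissue
  fit$identification <- identification
  fit$gamma <- gamma; fit$gamma_se <- se; fit$gamma_z <- zstat
  fit$gamma_log_p <- .log_two_sided(zstat)
  fit$gamma_p <- exp(fit$gamma_log_p)
  fit$loadings <- lam
  fit$resid_traits <- est[paste0("u_", traits)]
  fit$factor_var <- e_resid + gamma^2 * s2
  # gene effect per unit-variance factor, comparable across identifications
  fit$gamma_std_factor <- if (!is.null(gstd)) gstd[["value"]]
    else gamma / sqrt(fit$factor_var)
  fit$gamma_std_se <- if (!is.null(gstd)) gstd[["se"]] else NA_real_
  fit$var_explained <- g2s2 / (1 + g2s2)
  class(fit) <- c("tsem_gene_fit", class(fit))
  fit
}

#' Q_Gene heterogeneity test
#'
#' Two-step chi-square difference test of the null hypothesis that a gene's
#' expression affects the traits only through the common factor. Step 1
#' fits the common pathway model (one loading scaled to unity for
#' identification). Step 2 fits a common plus independent pathways model in
#' which the factor loadings and the gene effect on the factor are fixed at
#' their Step-1 estimates while direct gene-on-trait effects and all
#' residual variances are freely estimated. `Q = chisq1 - chisq2` with
#' `df = k - 1`. For comparability across models of different size the
#' statistic is also rescaled to a df = 1 chi-square by preserving its
#' p-value through the quantile transform.
#'
#' @param mat A `tsem_gene_matrices` object.
#' @param step1 Optional pre-computed unit-loading [fit_gene_on_factor()]
#'   fit (avoids refitting inside pipelines).
#' @param equal_loadings Passed to [fit_gene_on_factor()] when `step1` is
#'   not supplied.
#' @return List with `q` (chi-square), `df`, `p`, `log_p`, `q_chi1`, the
#'   two step fits, and `converged`.
#' @export
q_gene <- function(mat, step1 = NULL, equal_loadings = FALSE) {
  traits <- mat$traits
  k <- length(traits)
  if (is.null(step1))
    step1 <- fit_gene_on_factor(mat, "unit_loading",
                                equal_loadings = equal_loadings)
  if (!step1$converged)
    return(list(q = NA_real_, df = k - 1, p = NA_real_, log_p = NA_real_,
                q_chi1 = NA_real_, step1 = step1, step2 = NULL,
                converged = FALSE))
  lam <- step1$loadings
  syntax2 <- paste(
    c(paste("F =~", paste(sprintf("%.15g@%s", lam, traits), collapse = " + ")),
      sprintf("F ~ %.15g@gene", step1$gamma),
      sprintf("gene ~~ %.15g@gene", unname(mat$S["gene", "gene"])),
      "F ~~ e*F",
      paste0(traits, " ~ d_", traits, "*gene"),
      paste0(traits, " ~~ u_", traits, "*", traits)),
    collapse = "\n")
  step2 <- fit_dwls(mat$S, mat$V, syntax2)
  if (!step2$converged)
    return(list(q = NA_real_, df = k - 1, p = NA_real_, log_p = NA_real_,
                q_chi1 = NA_real_, step1 = step1, step2 = step2,
                converged = FALSE))
  q <- max(step1$chisq - step2$chisq, 0)
  df <- k - 1
  log_p <- stats::pchisq(q, df, lower.tail = FALSE, log.p = TRUE)
  q_chi1 <- chisq_to_df1(q, df)
  list(q = q, df = df, p = exp(log_p), log_p = log_p, q_chi1 = q_chi1,
       step1 = step1, step2 = step2, converged = TRUE)
}

#' Rescale a chi-square statistic to df = 1 preserving its p-value
#'
#' @param q Chi-square statistic.
#' @param df Its degrees of freedom.
#' @return The df = 1 chi-square with the same upper-tail probability.
#' @export
chisq_to_df1 <- function(q, df) {
  if (df == 1) return(q)
  log_p <- stats::pchisq(q, df, lower.tail = FALSE, log.p = TRUE)
  stats::qchisq(log_p, 1, lower.tail = FALSE, log.p = TRUE)
}

#' Full T-SEM analysis of one gene
#'
#' Runs the unit-loading common pathway fit and the Q_Gene two-step test,
#' returning one tidy row of results.
#'
#' @param mat A `tsem_gene_matrices` object.
#' @return A one-row `data.frame`: gene, tissue, gamma, se, p, chisq_q,
#'   df_q, p_q, chi1_q, converged.
#' @export
fit_tsem <- function(mat) {
  step1 <- fit_gene_on_factor(mat, "unit_loading")
  qg <- q_gene(mat, step1 = step1)
  data.frame(gene_id = mat$gene_id, tissue = mat$tissue,
             gamma = step1$gamma, se = step1$gamma_se,
             gamma_std = step1$gamma_std_factor,
             p = step1$gamma_p, log_p = step1$gamma_log_p,
             chisq_q = qg$q, df_q = qg$df, p_q = qg$p, log_p_q = qg$log_p,
             chi1_q = qg$q_chi1,
             converged = step1$converged && qg$converged,
             stringsAsFactors = FALSE)
}

#' Classify gene hits at a Bonferroni-corrected threshold
#'
#' Applies the threshold `alpha / n_tests` to the gene-on-factor p-values
#' and the Q_Gene p-values and assigns each gene to one of `factor-only`,
#' `q-only`, `both`, `neither`. The `factor_hit_reported` flag marks the
#' factor hits conventionally carried forward: significant for the factor
#' and \emph{not} significant for Q_Gene.
#'
#' @param fits `data.frame` as returned by [fit_tsem()] (rows bindable), or
#'   a list of such rows.
#' @param n_tests Total number of gene-tissue tests (e.g. 52849).
#' @param alpha Family-wise error level (default 0.05).
#' @return The input with columns `factor_hit`, `q_hit`, `class`,
#'   `factor_hit_reported` appended; attribute `threshold` carries the
#'   per-test threshold.
#' @export
classify_hits <- function(fits, n_tests, alpha = 0.05) {
  if (is.list(fits) && !is.data.frame(fits)) fits <- do.call(rbind, fits)
  if (n_tests < 1) stop("n_tests must be at least 1")
  thr <- alpha / n_tests
  if (nrow(fits) == 0) {
    out <- cbind(fits, factor_hit = logical(0), q_hit = logical(0),
                 class = character(0), factor_hit_reported = logical(0))
    attr(out, "threshold") <- thr
    return(out)
  }
  fits$factor_hit <- !is.na(fits$p) & fits$p < thr
  fits$q_hit <- !is.na(fits$p_q) & fits$p_q < thr
  fits$class <- ifelse(fits$factor_hit & fits$q_hit, "both",
                ifelse(fits$factor_hit, "factor-only",
                ifelse(fits$q_hit, "q-only", "neither")))
  fits$factor_hit_reported <- fits$factor_hit & !fits$q_hit
  attr(fits, "threshold") <- thr
  fits
}

#' Share of genetic overlap between two factors mediated by a gene
#'
#' Fits a two-factor model in which the gene predicts both factors and the
#' residual factor covariance is free, then evaluates the mediated share
#' `(b1 * s2 * b2) / (b1 * s2 * b2 + r_u)` as a ghost parameter with a
#' delta-method SE. Two-indicator factors use equality-constrained loadings
#' so the model is locally identified. Factor residual variances are fixed
#' to 1 (unit-variance identification).
#'
#' @param mat A `tsem_gene_matrices` object whose traits are the indicators
#'   of both factors.
#' @param factor1,factor2 Character vectors naming the indicators of each
#'   factor (subsets of `mat$traits`).
#' @return List with `percent_mediated`, `se` (both on the percent scale),
#'   and the underlying `fit`.
#' @export
mediation_share <- function(mat, factor1, factor2) {
  stopifnot(all(c(factor1, factor2) %in% mat$traits))
  load_terms <- function(inds, fac) {
    if (length(inds) == 2)
      paste0("l", fac, "*", inds)       # equality-constrained pair
    else paste0("l", fac, "_", inds, "*", inds)
  }
  s2 <- unname(mat$S["gene", "gene"])
  syntax <- paste(
    c(paste("G =~", paste(load_terms(factor1, "G"), collapse = " + ")),
      paste("P =~", paste(load_terms(factor2, "P"), collapse = " + ")),
      "G ~ b1*gene",
      "P ~ b2*gene",
      "G ~~ 1@G", "P ~~ 1@P",
      "G ~~ ru*P",
      sprintf("gene ~~ %.15g@gene", s2),
      paste0(mat$traits, " ~~ u_", mat$traits, "*", mat$traits)),
    collapse = "\n")
  fit <- fit_dwls(mat$S, mat$V, syntax)
  denom <- fit$estimates[["b1"]] * s2 * fit$estimates[["b2"]] +
    fit$estimates[["ru"]]
  if (abs(denom) < 1e-12)
    stop("total genetic covariance between the factors is ~0; ",
         "mediated share undefined")
  gp <- ghost_parameter(fit, "(b1 * s2 * b2) / (b1 * s2 * b2 + ru)",
                        extra = list(s2 = s2))
  list(percent_mediated = 100 * gp[["value"]], se = 100 * gp[["se"]],
       fit = fit)
}
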