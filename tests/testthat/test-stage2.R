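test_that("gene-on-factor fit recovers exact generating parameters", {
  lam <- c(0.45, 0.3, 0.5, 0.6, 0.35)
  names(lam) <- paste0("t", 1:5)
  u <- c(0.2, 0.3, 0.25, 0.15, 0.28)
  mat <- exact_gene_matrices(lam, u, gamma = 0.3, sigma2_gene = 0.1)

  f <- fit_gene_on_factor(mat, "unit_variance")
  expect_true(f$converged)
  expect_equal(f$gamma, 0.3, tolerance = 1e-6)
  expect_equal(unname(f$loadings), unname(lam), tolerance = 1e-6)
  expect_equal(unname(f$resid_traits), u, tolerance = 1e-6,
               ignore_attr = TRUE)

  # zero gene column -> gamma = 0
  mat0 <- mat
  mat0$S[1, -1] <- mat0$S[-1, 1] <- 0
  f0 <- fit_gene_on_factor(mat0, "unit_variance")
  expect_equal(f0$gamma, 0, tolerance = 1e-8)
})

test_that("unit-variance factor variance reproduces the 1 + gamma^2 rule", {
  lam <- c(0.5, 0.4, 0.45); names(lam) <- paste0("t", 1:3)
  u <- c(0.2, 0.3, 0.25)
  # sigma2_gene = 1 so the explained variance is gamma^2 itself
  mat <- exact_gene_matrices(lam, u, gamma = 0.05, sigma2_gene = 1)
  f <- fit_gene_on_factor(mat, "unit_variance")
  expect_equal(f$factor_var, 1 + 0.05^2, tolerance = 1e-6)
  expect_equal(f$factor_var, 1.0025, tolerance = 1e-6)
  expect_equal(f$var_explained, 0.05^2 / (1 + 0.05^2), tolerance = 1e-6)
})

test_that("identification modes agree on Z, chi-square and standardized fit", {
  lam <- c(0.45, 0.3, 0.5, 0.6, 0.35); names(lam) <- paste0("t", 1:5)
  u <- c(0.2, 0.3, 0.25, 0.15, 0.28)
  mat <- exact_gene_matrices(lam, u, gamma = 0.25, sigma2_gene = 0.1)
  # perturb so the model does not fit exactly
  mat$S[2, 1] <- mat$S[1, 2] <- mat$S[1, 2] + 3e-3
  mat$S[4, 3] <- mat$S[3, 4] <- mat$S[3, 4] - 5e-3

  ful <- fit_gene_on_factor(mat, "unit_loading")
  fuv <- fit_gene_on_factor(mat, "unit_variance")
  expect_equal(ful$gamma_z, fuv$gamma_z, tolerance = 1e-6)
  expect_equal(ful$gamma_p, fuv$gamma_p, tolerance = 1e-6)
  expect_equal(ful$chisq, fuv$chisq, tolerance = 1e-5)
  expect_equal(ful$gamma_std_factor, fuv$gamma_std_factor,
               tolerance = 1e-6)
  # loadings on the total-factor-sd scale agree across identifications
  expect_equal(unname(ful$loadings * sqrt(ful$factor_var)),
               unname(fuv$loadings * sqrt(fuv$factor_var)),
               tolerance = 1e-6)
})

test_that("gamma and Q_Gene do not depend on the anchor trait", {
  lam <- c(0.45, 0.3, 0.5, 0.6, 0.35); names(lam) <- paste0("t", 1:5)
  u <- c(0.2, 0.3, 0.25, 0.15, 0.28)
  mat <- exact_gene_matrices(lam, u, gamma = 0.25, sigma2_gene = 0.1)
  mat$S[3, 1] <- mat$S[1, 3] <- mat$S[1, 3] + 2e-3

  f_a <- fit_gene_on_factor(mat, "unit_loading", anchor = "t1")
  f_b <- fit_gene_on_factor(mat, "unit_loading", anchor = "t4")
  expect_equal(f_a$gamma_z, f_b$gamma_z, tolerance = 1e-5)
  q_a <- q_gene(mat, step1 = f_a)
  q_b <- q_gene(mat, step1 = f_b)
  expect_equal(q_a$q, q_b$q, tolerance = 1e-4)
})

test_that("Q_Gene is df = k-1 and the chi1 rescaling preserves p", {
  lam <- c(0.45, 0.3, 0.5, 0.6, 0.35); names(lam) <- paste0("t", 1:5)
  u <- c(0.2, 0.3, 0.25, 0.15, 0.28)
  mat <- exact_gene_matrices(lam, u, gamma = 0.25, sigma2_gene = 0.1)
  # heterogeneous gene effects: add a trait-specific deviation
  mat$S[2, 1] <- mat$S[1, 2] <- mat$S[1, 2] + 0.01
  qg <- q_gene(mat)
  expect_equal(qg$df, 4)
  expect_gt(qg$q, 0)
  expect_equal(stats::pchisq(qg$q_chi1, 1, lower.tail = FALSE), qg$p,
               tolerance = 1e-12)
  # monotonicity of the rescaling
  expect_gt(chisq_to_df1(30, 4), chisq_to_df1(20, 4))

  # exact factor-structured data: Q ~ 0
  mat2 <- exact_gene_matrices(lam, u, gamma = 0.25, sigma2_gene = 0.1)
  qg2 <- q_gene(mat2)
  expect_lt(qg2$q, 1e-4)
})

test_that("k = 2 with equality-constrained loadings gives df 1", {
  lam <- c(0.4, 0.4); names(lam) <- c("t1", "t2")
  u <- c(0.2, 0.2)
  mat <- exact_gene_matrices(lam, u, gamma = 0.3, sigma2_gene = 0.1)
  mat$S[2, 1] <- mat$S[1, 2] <- mat$S[1, 2] + 5e-3
  qg <- q_gene(mat, equal_loadings = TRUE)
  expect_equal(qg$df, 1)
  expect_equal(qg$q_chi1, qg$q, tolerance = 1e-10)
})

test_that("hits classify against the Bonferroni threshold", {
  thr_fits <- data.frame(
    gene_id = paste0("G", 1:4), tissue = "x",
    p = c(1e-9, 1e-9, 0.5, 1e-3),
    p_q = c(1e-9, 0.5, 1e-9, 0.9))
  out <- classify_hits(thr_fits, n_tests = 52849)
  expect_equal(attr(out, "threshold"), 0.05 / 52849)
  expect_equal(signif(attr(out, "threshold"), 3), 9.46e-7)
  expect_equal(out$class, c("both", "factor-only", "q-only", "neither"))
  expect_equal(out$factor_hit_reported, c(FALSE, TRUE, FALSE, FALSE))

  empty <- classify_hits(thr_fits[0, ], n_tests = 10)
  expect_equal(nrow(empty), 0)
})

test_that("mediation share matches direct evaluation of the ratio", {
  # two factors with two indicators each, equality-constrained loadings
  b1 <- 0.1; s2 <- 0.05; b2 <- -0.2; ru <- -0.099
  lg <- 0.5; lp <- 0.4
  vG <- 1 + b1^2 * s2; vP <- 1 + b2^2 * s2
  cGP <- b1 * s2 * b2 + ru
  traits <- c("g1", "g2", "p1", "p2")
  S <- matrix(0, 5, 5, dimnames = list(c("gene", traits),
                                       c("gene", traits)))
  S[1, 1] <- s2
  S["gene", c("g1", "g2")] <- b1 * s2 * lg
  S["gene", c("p1", "p2")] <- b2 * s2 * lp
  S[c("g1", "g2"), "gene"] <- S["gene", c("g1", "g2")]
  S[c("p1", "p2"), "gene"] <- S["gene", c("p1", "p2")]
  Sg <- lg^2 * vG; Sp <- lp^2 * vP
  S["g1", "g2"] <- S["g2", "g1"] <- Sg
  S["p1", "p2"] <- S["p2", "p1"] <- Sp
  for (g in c("g1", "g2")) for (p in c("p1", "p2")) {
    S[g, p] <- S[p, g] <- lg * lp * cGP
  }
  diag(S)[-1] <- c(Sg + 0.3, Sg + 0.3, Sp + 0.35, Sp + 0.35)
  V <- diag(15) * 1e-6
  mat <- structure(list(S = S, V = V, traits = traits, gene_id = "G",
                        tissue = "x", sigma2_gene = s2),
                   class = "tsem_gene_matrices")
  ms <- mediation_share(mat, factor1 = c("g1", "g2"),
                        factor2 = c("p1", "p2"))
  hand <- 100 * (b1 * s2 * b2) / (b1 * s2 * b2 + ru)
  expect_equal(ms$percent_mediated, hand, tolerance = 1e-4)
  expect_equal(hand, 1.0, tolerance = 0.01)
  expect_gt(ms$se, 0)

  # full mediation limit: r_u = 0 -> 100%
  ruf <- 0
  cGP2 <- b1 * s2 * b2 + ruf
  S2 <- S
  for (g in c("g1", "g2")) for (p in c("p1", "p2")) {
    S2[g, p] <- S2[p, g] <- lg * lp * cGP2
  }
  mat$S <- S2
  ms2 <- mediation_share(mat, c("g1", "g2"), c("p1", "p2"))
  expect_equal(ms2$percent_mediated, 100, tolerance = 1e-3)
})
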