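test_that("saturated and exactly identified models fit perfectly", {
  lam <- c(0.5, 0.6, 0.7); u <- c(0.3, 0.2, 0.4)
  fp <- factor_population(lam, u, v_fac = 0.25 / 0.25)
  S <- fp$S; V <- diag(6) * 1e-4

  # exactly identified one-factor model recovers generating parameters
  fit <- fit_dwls(S, V, "F =~ 1@t1 + l2*t2 + l3*t3\nF ~~ vF*F")
  expect_true(fit$converged)
  expect_equal(fit$estimates[["l2"]], lam[2] / lam[1], tolerance = 1e-6)
  expect_equal(fit$estimates[["l3"]], lam[3] / lam[1], tolerance = 1e-6)
  expect_equal(fit$estimates[["vF"]], lam[1]^2, tolerance = 1e-6)
  expect_equal(fit$chisq, 0, tolerance = 1e-8)
  expect_equal(fit$df, 0)

  # saturated model: Sigma = S exactly
  sat <- fit_dwls(S, V, paste(
    c("t1 ~~ a*t1", "t2 ~~ b*t2", "t3 ~~ c*t3",
      "t1 ~~ d*t2", "t1 ~~ e*t3", "t2 ~~ f*t3"), collapse = "\n"))
  expect_equal(sat$Sigma, S, tolerance = 1e-8)
  expect_equal(sat$chisq, 0, tolerance = 1e-10)
})

test_that("7-trait model recovers parameters and sandwich SEs calibrate", {
  set.seed(42)
  lam <- c(0.55, 0.4, 0.25, 0.5, 0.65, 0.35, 0.6)
  u <- c(0.4, 0.5, 0.6, 0.45, 0.3, 0.55, 0.35)
  fp <- factor_population(lam, u, n_eff = 500)

  # recovery on the exact model-implied matrix
  syn <- paste(c(paste("F =~", paste(paste0("l", 1:7, "*t", 1:7),
                                     collapse = " + ")),
                 "F ~~ 1@F"), collapse = "\n")
  fit <- fit_dwls(fp$S, fp$V, syn)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[paste0("l", 1:7)]), lam,
               tolerance = 1e-7)

  # Monte-Carlo check of the sandwich SEs
  root <- v_root(fp$V)
  mu <- vech(fp$S)
  reps <- 200
  est <- matrix(NA_real_, reps, 7)
  se1 <- numeric(reps)
  for (r in seq_len(reps)) {
    Sd <- draw_S(mu, root, fp$traits)
    Sd <- suppressWarnings(smooth_nearest_psd(Sd, floor = 1e-6))
    f <- fit_dwls(Sd, fp$V, syn)
    est[r, ] <- f$estimates[paste0("l", 1:7)]
    se1[r] <- f$se[["l1"]]
  }
  ratio <- mean(se1) / stats::sd(est[, 1])
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
  # loading estimates unbiased at MC precision
  expect_lt(abs(mean(est[, 1]) - lam[1]),
            4 * stats::sd(est[, 1]) / sqrt(reps))
})

test_that("model chi-square calibrates under the null and has power", {
  set.seed(7)
  lam <- c(0.6, 0.5, 0.45, 0.55)
  u <- c(0.3, 0.4, 0.45, 0.35)
  fp <- factor_population(lam, u, n_eff = 400)
  syn <- paste(c(paste("F =~", paste(paste0("l", 1:4, "*t", 1:4),
                                     collapse = " + ")),
                 "F ~~ 1@F"), collapse = "\n")
  root <- v_root(fp$V)
  mu <- vech(fp$S)
  reps <- 400
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    Sd <- draw_S(mu, root, fp$traits)
    Sd <- suppressWarnings(smooth_nearest_psd(Sd, floor = 1e-6))
    f <- fit_dwls(Sd, fp$V, syn)
    pvals[r] <- f$p
  }
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  # gross misspecification: a reversed-sign covariance is rejected
  S_bad <- fp$S
  S_bad[2, 1] <- S_bad[1, 2] <- -S_bad[1, 2]
  rej_bad <- mean(replicate(40, {
    Sd <- draw_S(vech(S_bad), root, fp$traits)
    Sd <- suppressWarnings(smooth_nearest_psd(Sd, floor = 1e-6))
    fit_dwls(Sd, fp$V, syn)$p < 0.05
  }))
  expect_gt(rej_bad, 0.9)
})

test_that("fit is invariant to permutation of S with a matching spec", {
  lam <- c(0.5, 0.6, 0.7, 0.4); u <- c(0.3, 0.2, 0.4, 0.5)
  fp <- factor_population(lam, u)
  # perturb so the fit is not exact
  S <- fp$S; S[2, 1] <- S[1, 2] <- S[1, 2] + 0.01
  syn <- function(ord) paste(
    c(paste("F =~", paste(paste0("l", ord, "*t", ord), collapse = " + ")),
      "F ~~ 1@F"), collapse = "\n")
  f1 <- fit_dwls(S, fp$V, syn(1:4))
  perm <- c(3, 1, 4, 2)
  Sp <- S[perm, perm]
  # vech entry q of Sp holds S[perm[i], perm[j]]; remap V accordingly
  pr <- vech_pairs(4)
  map <- vech_index(perm[pr[, "i"]], perm[pr[, "j"]], 4)
  Vp <- fp$V[map, map]
  f2 <- fit_dwls(Sp, Vp, syn(1:4))
  # the model addresses traits by name, so each trait keeps its loading
  expect_equal(f2$estimates[paste0("l", 1:4)],
               f1$estimates[paste0("l", 1:4)], tolerance = 1e-6)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-6)
})

test_that("ghost parameters evaluate with delta-method SEs", {
  lam <- c(0.5, 0.6, 0.7); u <- c(0.3, 0.2, 0.4)
  fp <- factor_population(lam, u)
  fit <- fit_dwls(fp$S, fp$V,
                  "F =~ l1*t1 + l2*t2 + l3*t3\nF ~~ 1@F")

  # identity expression reproduces the parameter and its own SE
  g1 <- ghost_parameter(fit, "l1")
  expect_equal(g1[["value"]], fit$estimates[["l1"]])
  expect_equal(g1[["se"]], fit$se[["l1"]], tolerance = 1e-6)

  # product of two loadings vs hand-computed delta method
  g12 <- ghost_parameter(fit, "l1 * l2")
  grad <- c(fit$estimates[["l2"]], fit$estimates[["l1"]])
  Vsub <- fit$vcov[c("l1", "l2"), c("l1", "l2")]
  expect_equal(g12[["value"]],
               fit$estimates[["l1"]] * fit$estimates[["l2"]])
  expect_equal(g12[["se"]], sqrt(drop(t(grad) %*% Vsub %*% grad)),
               tolerance = 1e-6)

  expect_error(ghost_parameter(fit, "l1 / (l2 - l2)"), "undefined")
})

test_that("optimizer is deterministic for identical inputs", {
  lam <- c(0.5, 0.6, 0.7); u <- c(0.3, 0.2, 0.4)
  fp <- factor_population(lam, u)
  S <- fp$S; S[3, 2] <- S[2, 3] <- S[2, 3] - 0.02
  syn <- "F =~ 1@t1 + l2*t2 + l3*t3\nF ~~ vF*F"
  f1 <- fit_dwls(S, fp$V, syn)
  f2 <- fit_dwls(S, fp$V, syn)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$chisq, f2$chisq)
})
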