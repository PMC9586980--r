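test_that("twas_z reduces correctly in closed-form cases", {
  ss <- toy_sumstats(5)
  ss$z <- c(2, 1, -1, 0.5, 3)
  R <- diag(5); dimnames(R) <- list(ss$snp_id, ss$snp_id)

  # single-SNP (top1) weight: TWAS Z equals that SNP's GWAS Z
  w1 <- eqtl_weights(data.frame(snp_id = "rs1", a1 = "A", a2 = "G",
                                weight = 2.5), "g1", sigma2_gene = 0.1,
                     n_train = 100)
  expect_equal(twas_z(w1, ss, R, ridge = 0), ss$z[1])

  # two SNPs, identity R, w = (1,1), z = (1,1) -> sqrt(2)
  ss2 <- ss; ss2$z <- c(1, 1, 0, 0, 0)
  w2 <- eqtl_weights(data.frame(snp_id = c("rs1", "rs2"), a1 = "A",
                                a2 = "G", weight = c(1, 1)), "g2",
                     sigma2_gene = 0.1, n_train = 100)
  expect_equal(twas_z(w2, ss2, R, ridge = 0), sqrt(2))

  # random 5-SNP weights vs brute-force quadratic form
  set.seed(21)
  Rf <- stats::cov2cor(crossprod(matrix(stats::rnorm(50), 10, 5)))
  dimnames(Rf) <- list(ss$snp_id, ss$snp_id)
  wts <- stats::rnorm(5)
  w5 <- eqtl_weights(data.frame(snp_id = ss$snp_id, a1 = "A", a2 = "G",
                                weight = wts), "g3", sigma2_gene = 0.1,
                     n_train = 100)
  brute <- sum(wts * ss$z) /
    sqrt(as.numeric(t(wts) %*% (Rf + 1e-3 * diag(5)) %*% wts))
  expect_equal(twas_z(w5, ss, Rf), brute)

  # weight allele swap flips the weight sign
  ssw <- ss; ssw$a1[1] <- "G"; ssw$a2[1] <- "A"
  expect_equal(twas_z(w1, ssw, R, ridge = 0), -ss$z[1])

  # > 50% missing weight SNPs: gene skipped
  w_miss <- eqtl_weights(data.frame(snp_id = c("rs1", "rsX", "rsY"),
                                    a1 = "A", a2 = "G",
                                    weight = c(1, 1, 1)), "g4",
                         sigma2_gene = 0.1, n_train = 100)
  z_skip <- twas_z(w_miss, ss, R)
  expect_true(is.na(z_skip))
  expect_true(isTRUE(attr(z_skip, "skipped")))
})

test_that("continuous rescaling matches the printed formulas", {
  out <- scale_continuous(z = 5, n = 10000, sigma2_gene = 0.05)
  expect_equal(out[["b"]], 5 / sqrt(500), tolerance = 1e-12)
  expect_equal(out[["b"]], 0.223607, tolerance = 1e-5)
  expect_equal(out[["se"]], 0.044721, tolerance = 1e-5)
  expect_equal(out[["cov"]], 0.011180, tolerance = 1e-4)

  z0 <- scale_continuous(0, 10000, 0.05)
  expect_equal(z0[["b"]], 0)
  expect_equal(z0[["cov"]], 0)
  expect_equal(z0[["se"]], 1 / sqrt(500))

  # scale equivariance: doubling sigma2 multiplies b, se by 1/sqrt(2)
  # and cov by sqrt(2)
  a <- scale_continuous(3, 5e4, 0.04)
  b <- scale_continuous(3, 5e4, 0.08)
  expect_equal(b[["b"]], a[["b"]] / sqrt(2))
  expect_equal(b[["se"]], a[["se"]] / sqrt(2))
  expect_equal(b[["cov"]], a[["cov"]] * sqrt(2))

  expect_error(scale_continuous(1, -5, 0.1), "positive")
})

test_that("binary rescaling applies the logistic standardization", {
  z0 <- scale_binary(0, 40000, 0.05)
  expect_equal(z0[["b"]], 0)
  expect_equal(z0[["se"]], (1 / sqrt(500)) / (pi / sqrt(3)))

  out <- scale_binary(4, 40000, 0.05)
  b_star <- 4 / sqrt(500)
  expect_equal(b_star, 0.178885, tolerance = 1e-5)
  divisor <- sqrt(0.05 * b_star^2 + pi^2 / 3)
  expect_equal(out[["b"]], b_star / divisor, tolerance = 1e-12)
  expect_equal(out[["se"]], (1 / sqrt(500)) / divisor, tolerance = 1e-12)
  expect_equal(out[["cov"]], out[["b"]] * 0.05)

  a <- scale_binary(3, 5e4, 0.04)
  b <- scale_binary(3, 5e4, 0.08)
  expect_equal(b[["cov"]] / a[["cov"]], sqrt(2), tolerance = 1e-3)
})

test_that("expanded matrices have the exact block structure", {
  cfg <- snp_sim_config(k = 3, m = 5000, seed = 17)
  ld <- make_ld_scores(cfg$m, seed = 17)
  set.seed(17)
  gen <- generate_gwas_z(cfg, ld = ld)
  est <- ldsc_core(gen$Z, matrix(cfg$n, cfg$m, 3), ld$l2, attr(ld, "M"),
                   n_blocks = 50)
  cov_gene <- c(0.01, -0.02, 0.005)
  se_gene <- c(0.05, 0.04, 0.06)
  s2 <- 0.12
  mat <- assemble_full_matrices(est, cov_gene, se_gene, s2,
                                gene_id = "G1")
  expect_equal(mat$S[1, 1], s2)
  expect_equal(unname(mat$S[-1, 1]), cov_gene)
  expect_equal(unname(mat$S[-1, -1]), unname(est$S))

  kk <- 4
  expect_equal(mat$V[1, 1], 1e-4)
  expect_true(all(mat$V[1, -1] == 0))
  gi <- vech_index(2:4, 1, kk)
  se_cov <- se_gene * s2
  expect_equal(diag(mat$V)[gi], se_cov^2)
  expect_equal(mat$V[gi[2], gi[1]], est$I[2, 1] * se_cov[1] * se_cov[2])
  # gene rows have zero sampling covariance with the LDSC block
  pr <- vech_pairs(3)
  li <- vech_index(pr[, "i"] + 1, pr[, "j"] + 1, kk)
  expect_true(all(mat$V[gi, li] == 0))
  expect_equal(mat$V[li, li], est$V)

  # zero intercepts -> diagonal gene block
  est0 <- est; est0$I[2, 1] <- est0$I[3, 1] <- est0$I[3, 2] <- 0
  mat0 <- assemble_full_matrices(est0, cov_gene, se_gene, s2)
  expect_true(all(mat0$V[gi, gi][lower.tri(diag(3))] == 0))

  expect_error(assemble_full_matrices(est, cov_gene[1:2], se_gene, s2),
               "length")
})

test_that("top1 weight conversion round-trips", {
  w <- top1_from_beqtl(0.442, 0.706, 144)
  expect_equal(w, 0.442 * 0.706 * sqrt(143))
  expect_equal(w, 3.7318, tolerance = 1e-4)
  expect_equal(beqtl_from_top1(w, 0.706, 144), 0.442, tolerance = 1e-12)
})
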