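# Deterministic generators for every input the pipeline consumes, so all
# tests and simulations run without any external download.

# Run code under a temporary RNG state so fixture generation never
# perturbs the caller's random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic LD score table
#'
#' Draws positive, right-skewed LD scores `l = 1 + Gamma(shape = 2)` with
#' mean `mean_l`, emulating the long right tail of genome-wide LD scores.
#' Deterministic for a given `(m, seed, mean_l)`.
#'
#' @param m Number of SNPs (at least 1000).
#' @param seed RNG seed.
#' @param mean_l Target mean LD score (closed-form mean of the generator).
#' @return LD score `data.frame` (`snp_id`, `l2`) with attribute `M = m`.
#' @export
make_ld_scores <- function(m, seed = 1, mean_l = 100) {
  if (m < 1000) stop("m must be at least 1000")
  l2 <- with_local_seed(seed,
    1 + stats::rgamma(m, shape = 2, scale = (mean_l - 1) / 2))
  out <- data.frame(snp_id = sprintf("rs%07d", seq_len(m)), l2 = l2,
                    stringsAsFactors = FALSE)
  attr(out, "M") <- m
  out
}

#' Synthetic functional-weight fixtures
#'
#' Generates `gene_count` multi-SNP weight sets plus one single-SNP
#' ("top1") gene whose stored weight is the inversion of the
#' top1-to-eQTL-effect relation, `w = b_eqtl * sigma_snp * sqrt(n - 1)`,
#' at the reference values `b_eqtl = 0.442`, `sigma_snp = 0.706`,
#' `n = 144`.
#'
#' @param gene_count Number of multi-SNP genes (0 allowed).
#' @param snps_per_gene SNPs per multi-SNP gene.
#' @param seed RNG seed.
#' @return List of `tsem_weights`; the top1 gene is named `G_TOP1` and
#'   carries `sigma2_gene = b_eqtl^2 sigma_snp^2`.
#' @export
make_weights <- function(gene_count = 3, snps_per_gene = 5, seed = 1) {
  sigma_snp <- 0.706; n_train <- 144; b_eqtl <- 0.442
  top1 <- eqtl_weights(
    weights = data.frame(snp_id = "rs_focal", a1 = "A", a2 = "G",
                         weight = top1_from_beqtl(b_eqtl, sigma_snp, n_train),
                         stringsAsFactors = FALSE),
    gene_id = "G_TOP1", tissue = "synthetic_panel",
    sigma2_gene = b_eqtl^2 * sigma_snp^2, n_train = n_train,
    cv_r2 = 0.8, model_tag = "top1")
  if (gene_count == 0) return(list(top1))
  rest <- with_local_seed(seed, lapply(seq_len(gene_count), function(g) {
    eqtl_weights(
      weights = data.frame(
        snp_id = sprintf("rs%07d", (g - 1) * snps_per_gene +
                           seq_len(snps_per_gene)),
        a1 = "A", a2 = "G",
        weight = stats::rnorm(snps_per_gene, 0, 0.3),
        stringsAsFactors = FALSE),
      gene_id = sprintf("G%04d", g), tissue = "synthetic_panel",
      sigma2_gene = stats::runif(1, 0.02, 0.2),
      n_train = 300, cv_r2 = stats::runif(1, 0.7, 0.95),
      model_tag = "enet")
  }))
  c(list(top1), rest)
}

#' Synthetic seven-trait population for the gene-expression simulator
#'
#' A stand-in for an empirically derived model-implied matrix: seven
#' positive loadings spanning a weak-to-strong range with a designated
#' smallest-loading trait (`rt`, the reaction-time analogue) and
#' largest-loading trait (`trailsb`), trait heritabilities between 0.10
#' and 0.25, a gene with expression variance `sigma2_gene` whose
#' standardized effect on the factor is `gamma_std` (so the model-implied
#' factor variance is `1 + gamma_std^2`, e.g. `1 + 0.05^2 = 1.0025` at the
#' default), and a block-structured sampling covariance: Wishart-form
#' sampling covariance for the trait block (effective df `n_eff`),
#' independent gene-trait sampling variances from the continuous-trait
#' TWAS scaling at GWAS size `n_gwas`, and the fixed small variance for
#' the gene's own variance. Everything is closed-form, hence byte-stable
#' across runs; `seed` is accepted for interface uniformity.
#'
#' @param seed Unused (generator is deterministic); kept for a stable
#'   fixture interface.
#' @param gamma_std Standardized gene effect on the factor
#'   (`gamma * sqrt(sigma2_gene)`).
#' @param sigma2_gene Gene expression variance.
#' @param n_gwas Per-trait GWAS sample size controlling gene-trait SEs.
#' @param n_eff Effective df of the trait-block sampling covariance.
#' @return List: `lambda`, `u`, `gamma`, `sigma2_gene`, `e`, `traits`,
#'   `smallest`, `largest`, `reverse_set`, `pop` (the model-implied
#'   matrix) and `V_obs`.
#' @export
make_seven_trait_population <- function(seed = 1, gamma_std = 0.05,
                                      sigma2_gene = 0.2, n_gwas = 100000,
                                      n_eff = 1000) {
  traits <- c("matrices", "memory", "rt", "sd", "trailsb", "tower", "vnr")
  std_load <- c(0.71, 0.56, 0.45, 0.64, 0.86, 0.49, 0.77)
  h2 <- c(0.21, 0.14, 0.10, 0.19, 0.25, 0.17, 0.22)
  names(std_load) <- names(h2) <- traits
  lambda <- std_load * sqrt(h2)
  u <- h2 * (1 - std_load^2)
  gamma <- gamma_std / sqrt(sigma2_gene)
  pop <- build_population(lambda, u, gamma, sigma2_gene, e = 1)

  kk <- length(traits) + 1
  p_star <- kk * (kk + 1) / 2
  V <- matrix(0, p_star, p_star)
  # gene variance: fixed small sampling variance, no cross-covariance
  V[1, 1] <- 1e-4
  # gene-trait rows: SE on the covariance scale from the TWAS rescaling
  se_cov <- sigma2_gene / sqrt(n_gwas * sigma2_gene)
  gi <- vech_index(seq_along(traits) + 1, 1, kk)
  V[cbind(gi, gi)] <- se_cov^2
  # trait block: Wishart-form sampling covariance at effective df n_eff
  pr <- vech_pairs(length(traits))
  ti <- vech_index(pr[, "i"] + 1, pr[, "j"] + 1, kk)
  St <- pop[-1, -1]
  for (a in seq_len(nrow(pr))) for (b in seq_len(a)) {
    i <- pr[a, "i"]; j <- pr[a, "j"]; l <- pr[b, "i"]; h <- pr[b, "j"]
    v <- (St[i, l] * St[j, h] + St[i, h] * St[j, l]) / n_eff
    V[ti[a], ti[b]] <- V[ti[b], ti[a]] <- v
  }
  list(lambda = lambda, u = u, gamma = gamma, sigma2_gene = sigma2_gene,
       e = 1, traits = traits, smallest = "rt", largest = "trailsb",
       reverse_set = c("matrices", "memory", "rt"), pop = pop, V_obs = V)
}

#' Write all fixture artifacts to a directory
#'
#' Emits the synthetic LD scores, a HapMap-style whitelist, the weight
#' tables, and per-trait summary statistics generated from the SNP-level
#' sampling model, as plain TSVs. Byte-identical for a given
#' `(preset, seed)`.
#'
#' @param dir Output directory (created if needed).
#' @param preset `"toy"` (m = 2000) or `"desk"` (m = 100000).
#' @param seed RNG seed.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, preset = c("toy", "desk"), seed = 1) {
  preset <- match.arg(preset)
  m <- if (preset == "toy") 2000 else 100000
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ld <- make_ld_scores(m, seed = seed)
  paths <- character(0)
  p <- file.path(dir, "ld_scores.tsv"); write_ld_scores(ld, p)
  paths <- c(paths, p)
  writeLines(ld$snp_id, file.path(dir, "hapmap_whitelist.txt"))
  paths <- c(paths, file.path(dir, "hapmap_whitelist.txt"))
  for (w in make_weights(seed = seed)) {
    p <- file.path(dir, paste0("weights_", w$gene_id, ".tsv"))
    write_weights(w, p); paths <- c(paths, p)
  }
  cfg <- snp_sim_config(m = m, seed = seed)
  gen <- with_local_seed(seed, generate_gwas_z(cfg, ld = ld))
  for (t in names(gen$sumstats)) {
    p <- file.path(dir, paste0("sumstats_", t, ".tsv"))
    write_sumstats(gen$sumstats[[t]], p); paths <- c(paths, p)
  }
  invisible(paths)
}
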