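# In-code fixtures shared across test files.

toy_sumstats <- function(n = 5) {
  data.frame(
    snp_id = paste0("rs", seq_len(n)),
    a1 = rep("A", n), a2 = rep("G", n),
    z = seq(-1, 1, length.out = n),
    n = 10000, maf = 0.25, info = 0.95,
    stringsAsFactors = FALSE)
}

# Exact gene-expanded matrices from known parameters, with a simple
# diagonal-ish V: gene-column SEs se_cov, Wishart-style trait block.
exact_gene_matrices <- function(lambda, u, gamma, sigma2_gene, e = 1,
                                se_cov = 1e-3, n_eff = 2000) {
  pop <- build_population(lambda, u, gamma, sigma2_gene, e = e)
  traits <- rownames(pop)[-1]
  kk <- nrow(pop)
  p_star <- kk * (kk + 1) / 2
  V <- matrix(0, p_star, p_star)
  V[1, 1] <- 1e-4
  gi <- vech_index(seq_along(traits) + 1, 1, kk)
  V[cbind(gi, gi)] <- se_cov^2
  pr <- vech_pairs(length(traits))
  ti <- vech_index(pr[, "i"] + 1, pr[, "j"] + 1, kk)
  St <- pop[-1, -1]
  for (a in seq_len(nrow(pr))) for (b in seq_len(a)) {
    i <- pr[a, "i"]; j <- pr[a, "j"]; l <- pr[b, "i"]; h <- pr[b, "j"]
    v <- (St[i, l] * St[j, h] + St[i, h] * St[j, l]) / n_eff
    V[ti[a], ti[b]] <- V[ti[b], ti[a]] <- v
  }
  structure(list(S = pop, V = V, traits = traits, gene_id = "Gtest",
                 tissue = "panel", sigma2_gene = sigma2_gene),
            class = "tsem_gene_matrices")
}

# One-factor population covariance and Wishart-form V for engine tests.
factor_population <- function(lambda, u, v_fac = 1, n_eff = 500) {
  k <- length(lambda)
  S <- v_fac * (lambda %o% lambda) + diag(u, k)
  traits <- paste0("t", seq_len(k))
  dimnames(S) <- list(traits, traits)
  pr <- vech_pairs(k)
  p_star <- nrow(pr)
  V <- matrix(0, p_star, p_star)
  for (a in seq_len(p_star)) for (b in seq_len(a)) {
    i <- pr[a, "i"]; j <- pr[a, "j"]; l <- pr[b, "i"]; h <- pr[b, "j"]
    val <- (S[i, l] * S[j, h] + S[i, h] * S[j, l]) / n_eff
    V[a, b] <- V[b, a] <- val
  }
  list(S = S, V = V, traits = traits)
}

# Draw an S matrix from N(vech(pop), V) given a precomputed root of V.
draw_S <- function(mu, root, labels) {
  unvech(mu + as.vector(root %*% stats::rnorm(ncol(root))), labels)
}

v_root <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)))
}
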