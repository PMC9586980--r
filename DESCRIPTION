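Package: tsem
Title: Transcriptome-Wide Structural Equation Modeling of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage multivariate transcriptome-wide association analysis
    (T-SEM) for genetically correlated GWAS traits. Stage 1 estimates a
    genetic covariance matrix and its block-jackknife sampling covariance
    from munged GWAS summary statistics via multivariable LD score
    regression, and expands both matrices with summary-based TWAS estimates
    of imputed gene expression. Stage 2 fits structural equation models to
    the expanded matrices by diagonally weighted least squares with sandwich
    standard errors, yielding the effect of tissue-specific gene expression
    on a latent factor, a chi-square heterogeneity statistic (Q_Gene) that
    flags genes whose effects do not operate through the factor, and a
    delta-method mediation share for genetic overlap between factors. Also
    provides the two simulation designs used to validate the method, a
    summary-based TWAS Z combiner for functional weights, and deterministic
    fixture generators so the full pipeline runs from synthetic inputs.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
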