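#' Quality-control filtering of GWAS summary statistics
#'
#' Standard pre-LDSC filtering: SNPs with minor allele frequency below
#' `maf_min` or imputation INFO below `info_min` are removed, and the table
#' is restricted to a whitelist of well-imputed SNPs (typically HapMap3).
#' Defaults follow common LDSC practice: MAF < 1\% and INFO < 0.9 removed.
#'
#' Rows with no INFO value are dropped under the default `info_policy =
#' "strict"` (conservative) and retained under `"permissive"`. Boundary SNPs
#' (exactly at a threshold) are kept: filters are applied as `maf >= maf_min`
#' and `info >= info_min`.
#'
#' The filters commute, so the per-filter drop counts attached to the result
#' (attribute `munge_report`) are counted marginally against the input.
#'
#' @param sumstats Summary-statistics `data.frame` (see [read_sumstats()]).
#' @param hapmap_whitelist Character vector of SNP ids to retain; required.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param info_min Minimum INFO score (default 0.9).
#' @param info_policy `"strict"` drops rows lacking INFO, `"permissive"`
#'   retains them.
#' @return The filtered table with attribute `munge_report`, a named vector
#'   of drop counts per filter.
#' @export
munge <- function(sumstats, hapmap_whitelist, maf_min = 0.01,
                  info_min = 0.9, info_policy = c("strict", "permissive")) {
  info_policy <- match.arg(info_policy)
  .required_cols(sumstats, c("snp_id", "a1", "a2", "z", "n", "maf"),
                 "sumstats table")
  if (length(hapmap_whitelist) == 0) stop("whitelist is empty")
  validate_sumstats(sumstats)

  maf_ok <- !is.na(sumstats$maf) & sumstats$maf >= maf_min
  if (is.null(sumstats$info)) {
    # no INFO column at all: the filter is not applicable (the strict
    # policy governs missing values within an existing column)
    if (info_min > 0)
      message("munge: no INFO column; INFO filter not applied")
    info_ok <- rep(TRUE, nrow(sumstats))
  } else {
    info_ok <- !is.na(sumstats$info) & sumstats$info >= info_min
    if (info_policy == "permissive") info_ok <- info_ok | is.na(sumstats$info)
  }
  wl_ok <- sumstats$snp_id %in% hapmap_whitelist

  report <- c(dropped_maf = sum(!maf_ok),
              dropped_info = sum(!info_ok),
              dropped_whitelist = sum(!wl_ok))
  out <- sumstats[maf_ok & info_ok & wl_ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("munge removed every SNP; output is empty")
  message(sprintf(
    "munge: %d of %d SNPs retained (dropped: maf %d, info %d, whitelist %d)",
    nrow(out), nrow(sumstats), report[1], report[2], report[3]))
  attr(out, "munge_report") <- report
  out
}

.AMBIGUOUS <- c("AT", "TA", "CG", "GC")

#' Align summary statistics across traits to a common allele reference
#'
#' Restricts a set of summary-statistics tables to their common SNPs, aligns
#' effect alleles to a reference allele map (flipping the sign of `z` — and
#' `beta` when present — where `a1`/`a2` are swapped relative to the
#' reference), and applies the TWAS-path MAF/INFO filters. Strand-ambiguous
#' SNPs (A/T, C/G) are dropped under the default strict policy, since their
#' orientation cannot be resolved without allele frequencies. SNPs whose
#' alleles are incompatible with the reference are dropped and counted,
#' never sign-guessed.
#'
#' @param tables List of two or more summary-statistics data.frames.
#' @param reference_alleles `data.frame` with columns `snp_id`, `a1`, `a2`
#'   giving the reference orientation.
#' @param maf_min Minimum MAF (default 0.01, applied per table).
#' @param info_min Minimum INFO (default 0.6; rows lacking INFO pass).
#' @param ambiguous_policy `"drop"` (default) removes strand-ambiguous SNPs;
#'   `"keep"` retains them.
#' @return List of aligned tables sharing one SNP id set, in the input
#'   order, with attribute `align_report`.
#' @export
align_for_twas <- function(tables, reference_alleles, maf_min = 0.01,
                           info_min = 0.6,
                           ambiguous_policy = c("drop", "keep")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  if (length(tables) < 2) stop("need at least two tables to align")
  ref <- reference_alleles
  .required_cols(ref, c("snp_id", "a1", "a2"), "reference allele map")

  dropped_ambiguous <- 0L
  dropped_incompatible <- 0L
  aligned <- lapply(tables, function(tab) {
    .required_cols(tab, c("snp_id", "a1", "a2", "z"), "sumstats table")
    keep <- rep(TRUE, nrow(tab))
    if (!is.null(tab$maf)) keep <- keep & tab$maf >= maf_min
    if (!is.null(tab$info)) keep <- keep & (is.na(tab$info) |
                                              tab$info >= info_min)
    tab <- tab[keep, , drop = FALSE]
    m <- match(tab$snp_id, ref$snp_id)
    tab <- tab[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
    ra1 <- toupper(ref$a1[m]); ra2 <- toupper(ref$a2[m])
    a1 <- toupper(tab$a1); a2 <- toupper(tab$a2)

    amb <- paste0(a1, a2) %in% .AMBIGUOUS
    same <- a1 == ra1 & a2 == ra2
    swap <- a1 == ra2 & a2 == ra1
    incompat <- !(same | swap)
    dropped_incompatible <<- dropped_incompatible + sum(incompat & !amb)
    if (ambiguous_policy == "drop") {
      dropped_ambiguous <<- dropped_ambiguous + sum(amb & !incompat)
      ok <- (same | swap) & !amb
    } else {
      ok <- same | swap
    }
    tab <- tab[ok, , drop = FALSE]
    flip <- swap[ok]
    tab$z[flip] <- -tab$z[flip]
    if (!is.null(tab$beta)) tab$beta[flip] <- -tab$beta[flip]
    # every surviving row now carries the reference orientation
    tab$a1 <- ra1[ok]
    tab$a2 <- ra2[ok]
    tab
  })

  common <- Reduce(intersect, lapply(aligned, `[[`, "snp_id"))
  out <- lapply(aligned, function(tab) {
    tab <- tab[match(common, tab$snp_id), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
  attr(out, "align_report") <- c(
    n_common = length(common),
    dropped_ambiguous = dropped_ambiguous,
    dropped_incompatible = dropped_incompatible)
  message(sprintf(
    "align: %d SNPs common to %d tables (dropped %d ambiguous, %d incompatible)",
    length(common), length(tables), dropped_ambiguous, dropped_incompatible))
  out
}
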