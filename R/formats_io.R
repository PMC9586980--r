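# Plain-TSV readers and writers for the table types the pipeline consumes.
# All tables are tab-delimited with a header row; SNPs are keyed by rsID only.

.required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read / write GWAS summary statistics
#'
#' A summary-statistics table has columns `snp_id`, `a1`, `a2`, `z`, `n`,
#' `maf`, and optionally `info`, `beta`, `se`. `a1` is the effect allele to
#' which `z` (and `beta`) are signed. When both `beta` and `se` are present,
#' `z` must equal `beta/se` up to floating-point tolerance.
#'
#' @param path File path of a tab-delimited table with header.
#' @return A `data.frame` with one row per SNP.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .required_cols(df, c("snp_id", "a1", "a2", "z", "n", "maf"), "sumstats table")
  validate_sumstats(df)
  df
}

#' @rdname read_sumstats
#' @param sumstats Summary-statistics `data.frame`.
#' @export
write_sumstats <- function(sumstats, path) {
  validate_sumstats(sumstats)
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a summary-statistics table
#'
#' Checks the invariants: unique SNP ids, MAF within [0, 0.5], INFO within
#' [0, 1] where present, and `z = beta/se` when both are present.
#'
#' @param sumstats Summary-statistics `data.frame`.
#' @return The table, invisibly.
#' @export
validate_sumstats <- function(sumstats) {
  if (anyDuplicated(sumstats$snp_id))
    stop("duplicate snp_id in sumstats table")
  if (any(sumstats$maf < 0 | sumstats$maf > 0.5, na.rm = TRUE))
    stop("maf outside [0, 0.5]")
  if (!is.null(sumstats$info) &&
      any(sumstats$info < 0 | sumstats$info > 1, na.rm = TRUE))
    stop("info outside [0, 1]")
  if (!is.null(sumstats$beta) && !is.null(sumstats$se)) {
    ok <- is.na(sumstats$beta) | is.na(sumstats$se) |
      abs(sumstats$z - sumstats$beta / sumstats$se) < 1e-6 *
        pmax(1, abs(sumstats$z))
    if (!all(ok)) stop("z does not equal beta/se")
  }
  invisible(sumstats)
}

#' Read / write an LD score table
#'
#' Per-SNP LD scores (`snp_id`, `l2`) plus the scalar `M`, the total SNP
#' count used as the regression denominator. `M` is stored in a plain-text
#' sidecar file `<path>.M` (one number), mirroring the convention of LD score
#' distributions, and carried on the returned object as attribute `M`.
#'
#' @param path File path of the tab-delimited LD score table.
#' @return A `data.frame` with columns `snp_id`, `l2` and attribute `M`.
#' @export
read_ld_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .required_cols(df, c("snp_id", "l2"), "LD score table")
  if (any(df$l2 < 0)) stop("negative LD score")
  mpath <- paste0(path, ".M")
  M <- if (file.exists(mpath)) as.numeric(readLines(mpath)[1]) else nrow(df)
  if (M < nrow(df)) stop("M smaller than the number of LD score rows")
  attr(df, "M") <- M
  df
}

#' @rdname read_ld_scores
#' @param ld LD score `data.frame` with attribute `M` (defaults to row count).
#' @export
write_ld_scores <- function(ld, path) {
  M <- attr(ld, "M")
  if (is.null(M)) M <- nrow(ld)
  utils::write.table(ld[, c("snp_id", "l2")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(format(M, scientific = FALSE), paste0(path, ".M"))
  invisible(path)
}

#' Read / write functional (eQTL) weights
#'
#' Weights are consumed as a text export: a per-SNP table (`snp_id`, `a1`,
#' `a2`, `weight`) plus per-gene metadata (`gene_id`, `tissue`,
#' `sigma2_gene`, `n_train`, `cv_r2`, `model_tag`) stored in a companion
#' file `<path>.meta`. The binary FUSION weight format is deliberately not
#' parsed.
#'
#' @param path File path of the tab-delimited weight table.
#' @return A list of class `tsem_weights` with elements `weights`
#'   (data.frame) and the metadata fields.
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .required_cols(df, c("snp_id", "a1", "a2", "weight"), "weight table")
  meta <- utils::read.delim(paste0(path, ".meta"), stringsAsFactors = FALSE)
  .required_cols(meta, c("gene_id", "tissue", "sigma2_gene", "n_train"),
                 "weight metadata")
  eqtl_weights(weights = df, gene_id = meta$gene_id[1],
               tissue = meta$tissue[1], sigma2_gene = meta$sigma2_gene[1],
               n_train = meta$n_train[1],
               cv_r2 = if ("cv_r2" %in% names(meta)) meta$cv_r2[1] else NA,
               model_tag = if ("model_tag" %in% names(meta))
                 meta$model_tag[1] else NA)
}

#' @rdname read_weights
#' @param w A `tsem_weights` object.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "tsem_weights"))
  utils::write.table(w$weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(gene_id = w$gene_id, tissue = w$tissue,
                     sigma2_gene = w$sigma2_gene, n_train = w$n_train,
                     cv_r2 = w$cv_r2, model_tag = w$model_tag)
  utils::write.table(meta, paste0(path, ".meta"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a functional-weight object
#'
#' @param weights data.frame with `snp_id`, `a1`, `a2`, `weight`.
#' @param gene_id,tissue Gene and expression-panel labels.
#' @param sigma2_gene Cis-heritability of expression (variance of the
#'   genetically imputed expression, on the standardized-expression scale).
#' @param n_train Expression-panel sample size the weights were trained on.
#' @param cv_r2 Cross-validation R-squared of the weight model (optional).
#' @param model_tag Which penalized model produced the weights (optional).
#' @return Object of class `tsem_weights`.
#' @export
eqtl_weights <- function(weights, gene_id, tissue = "panel",
                         sigma2_gene, n_train, cv_r2 = NA, model_tag = NA) {
  if (sigma2_gene <= 0) stop("sigma2_gene must be positive")
  if (all(weights$weight == 0)) stop("all weights are zero")
  structure(list(weights = weights, gene_id = gene_id, tissue = tissue,
                 sigma2_gene = sigma2_gene, n_train = n_train,
                 cv_r2 = cv_r2, model_tag = model_tag),
            class = "tsem_weights")
}

#' Read / write a univariate TWAS output table
#'
#' The minimal columns are `gene_id`, `tissue`, `sigma2_gene` (column `HSQ`
#' is accepted as an alias) and one `TWAS.Z` column per trait file. Extra
#' columns are preserved.
#'
#' @param path File path of the tab-delimited TWAS output table.
#' @return A `data.frame`.
#' @export
read_twas_output <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("HSQ" %in% names(df) && !"sigma2_gene" %in% names(df))
    names(df)[names(df) == "HSQ"] <- "sigma2_gene"
  if ("ID" %in% names(df) && !"gene_id" %in% names(df))
    names(df)[names(df) == "ID"] <- "gene_id"
  if ("PANEL" %in% names(df) && !"tissue" %in% names(df))
    names(df)[names(df) == "PANEL"] <- "tissue"
  .required_cols(df, c("gene_id", "TWAS.Z"), "TWAS output table")
  df$TWAS.Z <- as.numeric(df$TWAS.Z)
  df
}

#' @rdname read_twas_output
#' @param twas TWAS output `data.frame`.
#' @export
write_twas_output <- function(twas, path) {
  utils::write.table(twas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
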