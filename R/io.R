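.ssf_cols <- c(
  variant_id = "variant_id", chromosome = "chromosome", position = "base_pair_location",
  effect_allele = "effect_allele", other_allele = "other_allele",
  eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
  p_value = "p_value", n = "n"
)

#' Write GWAS summary statistics as a standard-format TSV
#'
#' One row per variant with the fixed header `variant_id chromosome
#' base_pair_location effect_allele other_allele effect_allele_frequency beta
#' standard_error p_value n`; missing values are written as `NA`.
#'
#' @param stats Association table (see [run_gwas()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- stats[, names(.ssf_cols)]
  names(out) <- unname(.ssf_cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read GWAS summary statistics from a standard-format TSV
#'
#' @param path Input path (header as written by [write_sumstats()]).
#' @param trait_label Label for the `trait` column.
#' @return Association data frame with the package's internal column names.
#' @export
read_sumstats <- function(path, trait_label = basename(path)) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(.ssf_cols), names(raw))
  if (length(missing)) stop("summary-statistic file lacks columns: ",
                            paste(missing, collapse = ", "))
  out <- raw[, unname(.ssf_cols)]
  names(out) <- names(.ssf_cols)
  out$trait <- trait_label
  out
}

#' Write a dosage matrix and its variant sidecar as TSV
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param variants Variant table.
#' @param prefix Path prefix; writes `<prefix>_dosages.tsv` and
#'   `<prefix>_variants.tsv`.
#' @param ids Optional individual ids (first column of the dosage file).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_dosages <- function(genotypes, variants, prefix, ids = NULL) {
  d <- as.data.frame(genotypes)
  if (!is.null(ids)) d <- cbind(individual_id = ids, d)
  dp <- paste0(prefix, "_dosages.tsv")
  vp <- paste0(prefix, "_variants.tsv")
  utils::write.table(d, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(variants), vp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosages = dp, variants = vp))
}

#' Write hard-call genotypes as a minimal VCF (GT field only)
#'
#' @param genotypes Integer dosage matrix with values in `{0, 1, 2}`.
#' @param variants Variant table (effect allele written as ALT).
#' @param path Output path.
#' @param ids Optional sample ids.
#' @return `path`, invisibly.
#' @export
write_minimal_vcf <- function(genotypes, variants, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(nrow(genotypes)))
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(nrow(variants))) {
    row <- paste(c(variants$chromosome[j], variants$position[j], variants$variant_id[j],
                   variants$other_allele[j], variants$effect_allele[j], ".", "PASS",
                   ".", "GT", gt[genotypes[, j] + 1L]), collapse = "\t")
    writeLines(row, con)
  }
  invisible(path)
}

#' Write the ground truth of a simulated study
#'
#' A per-variant TSV of true effect vectors followed by a key-value block of
#' the scalar causal parameters (written as comment lines at the top).
#'
#' @param bundle A `study_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(bundle, path) {
  tr <- bundle$truth
  kv <- c(
    sprintf("# phi\t%.17g", tr$phi),
    sprintf("# theta_child\t%.17g", tr$theta_child),
    sprintf("# theta_adult\t%.17g", tr$theta_adult),
    sprintf("# confounder_child\t%.17g", tr$confounder_loadings[["child"]]),
    sprintf("# confounder_adult\t%.17g", tr$confounder_loadings[["adult"]]),
    sprintf("# confounder_outcome\t%.17g", tr$confounder_loadings[["outcome"]]),
    sprintf("# outcome_type\t%s", tr$outcome_type),
    sprintf("# binary_prevalence\t%s",
            if (is.null(tr$binary_prevalence)) "NA" else sprintf("%.17g", tr$binary_prevalence))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(kv, con)
  utils::write.table(bundle$effects, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a manifest of output files with content hashes
#'
#' @param files Character vector of file paths.
#' @param path Manifest path.
#' @param meta Named character vector of run metadata (seed, config hash, ...).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(files, path, meta = character()) {
  md5 <- tools::md5sum(files)
  lines <- c(
    paste0("# ", names(meta), "\t", meta),
    paste(basename(files), unname(md5), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
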