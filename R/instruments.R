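#' Greedy LD clumping of association statistics
#'
#' Variants failing the p-value or MAF filters are dropped; the remaining
#' variants are scanned greedily: the smallest-p variant becomes an index and
#' every remaining variant on the same chromosome that is BOTH within
#' `window_kb` of it AND correlated above `r2_thresh` is removed; repeat until
#' exhausted. Cross-chromosome r-squared is treated as 0, so removal requires
#' proximity and correlation together. Ties on p are broken by (chromosome,
#' position, variant id) for reproducibility.
#'
#' @param stats Association table from [run_gwas()] (needs `chromosome`,
#'   `position`, `eaf`, `p_value`).
#' @param ld r-squared matrix from [ld_r2()] covering the tested variants.
#' @param p_thresh Significance threshold (default genome-wide, 5e-8).
#' @param r2_thresh Independence threshold on r-squared.
#' @param window_kb Distance window in kilobases.
#' @param maf_bounds Inclusive bounds on effect-allele frequency.
#' @return An `instrument_set`: list with the retained rows (`stats`, with a
#'   `clump_index` rank column), the selection `params`, `variance_explained`
#'   (total, from [variance_explained()]) and `mean_f` (from
#'   [mean_f_statistic()]). Empty selection gives a zero-row set with a
#'   warning.
#' @export
clump <- function(stats, ld, p_thresh = 5e-8, r2_thresh = 0.001,
                  window_kb = 250, maf_bounds = c(0.01, 0.99)) {
  need <- c("variant_id", "chromosome", "position", "eaf", "p_value")
  stopifnot(all(need %in% names(stats)))
  ok <- !is.na(stats$p_value) & stats$p_value <= p_thresh &
    stats$eaf >= maf_bounds[1] & stats$eaf <= maf_bounds[2]
  pool <- stats[ok, , drop = FALSE]
  params <- list(p_thresh = p_thresh, r2_thresh = r2_thresh,
                 window_kb = window_kb, maf_bounds = maf_bounds)
  if (!nrow(pool)) {
    warning("no variants pass the p/MAF filters; empty instrument set")
    return(new_instrument_set(stats[0, , drop = FALSE], params))
  }
  ord <- order(pool$p_value, pool$chromosome, pool$position, pool$variant_id)
  pool <- pool[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(pool))
  index <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (!alive[i]) next
    index[i] <- TRUE
    same_chr <- pool$chromosome == pool$chromosome[i]
    near <- abs(pool$position - pool$position[i]) <= window_kb * 1000
    r2 <- ld[pool$variant_id[i], pool$variant_id]
    alive[alive & same_chr & near & r2 > r2_thresh] <- FALSE
    alive[i] <- FALSE
  }
  sel <- pool[index, , drop = FALSE]
  sel$clump_index <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  new_instrument_set(sel, params)
}

new_instrument_set <- function(stats, params) {
  structure(list(
    trait = if (nrow(stats)) stats$trait[1] else NA_character_,
    stats = stats,
    params = params,
    variance_explained = if (nrow(stats)) sum(variance_explained(stats$beta, stats$eaf)) else 0,
    mean_f = if (nrow(stats)) mean((stats$beta / stats$se)^2) else NA_real_
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument set '%s': %d variants, variance explained %.4f, mean F %.1f\n",
              x$trait, nrow(x$stats), x$variance_explained, x$mean_f))
  invisible(x)
}

#' Variance in a unit-variance trait explained by a variant
#'
#' `2 * beta^2 * eaf * (1 - eaf)` for an additive biallelic effect on a
#' standardised trait; summed over an instrument set it gives the set's total
#' variance explained.
#'
#' @param beta Per-allele effect (SD units).
#' @param eaf Effect-allele frequency strictly in (0, 1).
#' @return Variance explained (same length as the inputs).
#' @export
variance_explained <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie strictly in (0, 1)")
  2 * beta^2 * eaf * (1 - eaf)
}

#' Mean per-variant Wald F-statistic of an instrument set
#'
#' Mean over instruments of `(beta / se)^2`, the single-regressor Wald form;
#' F above 10 is the conventional adequacy rule of thumb.
#'
#' @param instruments An `instrument_set` or an association data frame with
#'   `beta` and `se`.
#' @return Mean F.
#' @export
mean_f_statistic <- function(instruments) {
  stats <- if (inherits(instruments, "instrument_set")) instruments$stats else instruments
  if (!nrow(stats)) stop("empty instrument set")
  if (any(stats$se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  mean((stats$beta / stats$se)^2)
}

#' Validate a genetic risk score against a phenotype
#'
#' The score is the beta-weighted dosage sum over the instruments. The report
#' mirrors a standard score validation: the odds ratio per SD of score for the
#' standardised phenotype exceeding +1 SD (logistic fit, Wald CI and p), the
#' area under the ROC curve of the score against that binary target
#' (rank-based Mann-Whitney computation, ties at half weight), and the squared
#' correlation of score and continuous phenotype.
#'
#' @param instruments An `instrument_set` (at least 2 variants present in the
#'   genotype matrix).
#' @param genotypes Dosage matrix of the validation cohort.
#' @param phenotype Continuous phenotype vector; standardised internally.
#' @return List with `odds_ratio`, `or_ci`, `or_p`, `auc`,
#'   `variance_explained`, `n`, `n_cases`, `n_instruments`.
#' @export
grs_validate <- function(instruments, genotypes, phenotype) {
  stats <- instruments$stats
  present <- intersect(stats$variant_id, colnames(genotypes))
  if (length(present) < 2) stop("fewer than 2 instruments present in the genotype matrix")
  w <- stats$beta[match(present, stats$variant_id)]
  score <- drop(genotypes[, present, drop = FALSE] %*% w)
  score_z <- (score - mean(score)) / stats::sd(score)
  ph_z <- (phenotype - mean(phenotype)) / stats::sd(phenotype)
  case <- ph_z > 1
  if (!any(case)) stop("no cases above +1 SD of the phenotype")
  fit <- stats::glm(case ~ score_z, family = stats::binomial())
  cf <- summary(fit)$coefficients["score_z", ]
  list(
    odds_ratio = exp(cf["Estimate"]),
    or_ci = exp(cf["Estimate"] + c(-1, 1) * 1.96 * cf["Std. Error"]),
    or_p = 2 * stats::pnorm(-abs(cf["Estimate"] / cf["Std. Error"])),
    auc = auc_rank(score_z, case),
    variance_explained = stats::cor(score, phenotype)^2,
    n = length(phenotype),
    n_cases = sum(case),
    n_instruments = length(present)
  )
}

#' Area under the ROC curve by the Mann-Whitney rank statistic
#'
#' @param score Numeric scores.
#' @param case Logical case indicator.
#' @return AUC in `[0, 1]`; ties contribute half weight via average ranks.
#' @export
auc_rank <- function(score, case) {
  case <- as.logical(case)
  n1 <- sum(case)
  n0 <- sum(!case)
  if (n1 == 0 || n0 == 0) stop("both cases and controls are required")
  r <- rank(score, ties.method = "average")
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
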