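.palindromic <- function(a1, a2) {
  paste(a1, a2) %in% c("A T", "T A", "C G", "G C")
}

#' Harmonise exposure and outcome summary statistics to a common effect allele
#'
#' Rows with identical allele pairs are kept as-is; rows whose alleles are
#' swapped between the tables get the outcome beta negated and the outcome
#' frequency complemented. Palindromic variants (A/T, C/G) cannot be oriented
#' from alleles alone: they are kept only when, after allele orientation, both
#' reported frequencies fall on the same side of 0.5 and outside the ambiguity
#' band `[palindrome_maf_limit, 1 - palindrome_maf_limit]`; otherwise they are
#' dropped. Non-palindromic rows whose oriented frequencies disagree by more
#' than `freq_tol` are dropped. Allele mismatches are dropped with a reason
#' code. Dropped rows are recorded in the `dropped` attribute.
#'
#' @param exposure,outcome Association tables (see [run_gwas()]) keyed by
#'   `variant_id` with allele and `eaf` columns; no duplicated ids.
#' @param freq_tol Tolerated absolute frequency difference for
#'   non-palindromic variants.
#' @param palindrome_maf_limit Lower edge of the palindrome ambiguity band.
#' @return A `harmonised_set` data frame: `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `eaf`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `flipped`, `proxy_used`.
#' @export
harmonise <- function(exposure, outcome, freq_tol = 0.08, palindrome_maf_limit = 0.42) {
  for (tab in list(exposure, outcome)) {
    if (!all(c("variant_id", "effect_allele", "other_allele", "eaf") %in% names(tab))) {
      stop("harmonise needs variant_id, effect_allele, other_allele, eaf in both tables")
    }
    if (anyDuplicated(tab$variant_id)) stop("duplicated variant ids")
  }
  m <- merge(exposure, outcome, by = "variant_id", suffixes = c("_exp", "_out"))
  if (!nrow(m)) {
    return(empty_harmonised())
  }
  aligned <- m$effect_allele_exp == m$effect_allele_out & m$other_allele_exp == m$other_allele_out
  swapped <- m$effect_allele_exp == m$other_allele_out & m$other_allele_exp == m$effect_allele_out
  reason <- rep(NA_character_, nrow(m))
  reason[!aligned & !swapped] <- "allele_mismatch"

  beta_out <- ifelse(swapped, -m$beta_out, m$beta_out)
  eaf_out <- ifelse(swapped, 1 - m$eaf_out, m$eaf_out)

  pal <- .palindromic(m$effect_allele_exp, m$other_allele_exp)
  lim <- c(palindrome_maf_limit, 1 - palindrome_maf_limit)
  informative <- (m$eaf_exp < lim[1] | m$eaf_exp > lim[2]) &
    (eaf_out < lim[1] | eaf_out > lim[2])
  same_side <- (m$eaf_exp - 0.5) * (eaf_out - 0.5) > 0
  drop_pal <- pal & !(informative & same_side)
  reason[is.na(reason) & drop_pal] <- "ambiguous_palindrome"
  drop_freq <- !pal & abs(m$eaf_exp - eaf_out) > freq_tol
  reason[is.na(reason) & drop_freq] <- "eaf_mismatch"

  keep <- is.na(reason)
  out <- data.frame(
    variant_id = m$variant_id[keep],
    chromosome = if ("chromosome_exp" %in% names(m)) m$chromosome_exp[keep] else NA_integer_,
    position = if ("position_exp" %in% names(m)) m$position_exp[keep] else NA_integer_,
    effect_allele = m$effect_allele_exp[keep],
    other_allele = m$other_allele_exp[keep],
    eaf = m$eaf_exp[keep],
    beta_exposure = m$beta_exp[keep],
    se_exposure = m$se_exp[keep],
    beta_outcome = beta_out[keep],
    se_outcome = m$se_out[keep],
    flipped = swapped[keep],
    proxy_used = FALSE,
    stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- data.frame(
    variant_id = m$variant_id[!keep], reason = reason[!keep], stringsAsFactors = FALSE
  )
  class(out) <- c("harmonised_set", "data.frame")
  out
}

empty_harmonised <- function() {
  out <- data.frame(
    variant_id = character(), chromosome = integer(), position = integer(),
    effect_allele = character(), other_allele = character(), eaf = numeric(),
    beta_exposure = numeric(), se_exposure = numeric(),
    beta_outcome = numeric(), se_outcome = numeric(),
    flipped = logical(), proxy_used = logical(), stringsAsFactors = FALSE
  )
  attr(out, "dropped") <- data.frame(variant_id = character(), reason = character())
  class(out) <- c("harmonised_set", "data.frame")
  out
}

#' Harmonise two exposures and an outcome for multivariable MR
#'
#' The second exposure's effects are first oriented to the first exposure's
#' effect alleles, then the outcome is oriented the same way; only variants
#' with measured effects in all three tables are retained (never
#' zero-imputed).
#'
#' @param exposure1,exposure2 Exposure association tables.
#' @param outcome Outcome association table.
#' @inheritParams harmonise
#' @return Data frame with `beta_exposure1/se_exposure1`,
#'   `beta_exposure2/se_exposure2`, `beta_outcome/se_outcome` plus the allele
#'   and location columns, class `harmonised_set`.
#' @export
harmonise_mvmr <- function(exposure1, exposure2, outcome,
                           freq_tol = 0.08, palindrome_maf_limit = 0.42) {
  h12 <- harmonise(exposure1, exposure2, freq_tol, palindrome_maf_limit)
  h1y <- harmonise(exposure1, outcome, freq_tol, palindrome_maf_limit)
  common <- intersect(h12$variant_id, h1y$variant_id)
  a <- h12[match(common, h12$variant_id), ]
  b <- h1y[match(common, h1y$variant_id), ]
  out <- data.frame(
    variant_id = common,
    chromosome = a$chromosome, position = a$position,
    effect_allele = a$effect_allele, other_allele = a$other_allele,
    eaf = a$eaf,
    beta_exposure1 = a$beta_exposure, se_exposure1 = a$se_exposure,
    beta_exposure2 = a$beta_outcome, se_exposure2 = a$se_outcome,
    beta_outcome = b$beta_outcome, se_outcome = b$se_outcome,
    flipped = b$flipped, proxy_used = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonised_set", "data.frame")
  out
}

#' Find an LD proxy for a missing variant
#'
#' Returns the available variant with the highest r-squared to the target,
#' subject to r-squared strictly above `r2_min` and distance at most
#' `window_kb`; ties are broken by distance then id. Absence of a qualifying
#' proxy is a valid result (`NA`).
#'
#' @param target Variant id to be proxied.
#' @param available Character vector of candidate variant ids.
#' @param ld r-squared matrix covering target and candidates.
#' @param variants Variant table with `chromosome` and `position`.
#' @param r2_min Strict lower bound on r-squared.
#' @param window_kb Maximum distance in kilobases.
#' @return The proxy's variant id, or `NA_character_`.
#' @export
find_proxy <- function(target, available, ld, variants, r2_min = 0.8, window_kb = 250) {
  vt <- variants[match(c(target, available), variants$variant_id), ]
  tgt <- vt[1, ]
  cand <- vt[-1, , drop = FALSE]
  ok <- cand$chromosome == tgt$chromosome &
    abs(cand$position - tgt$position) <= window_kb * 1000
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  r2 <- ld[target, cand$variant_id]
  qual <- r2 > r2_min
  if (!any(qual)) return(NA_character_)
  cand <- cand[qual, , drop = FALSE]
  r2 <- r2[qual]
  dist <- abs(cand$position - tgt$position)
  cand$variant_id[order(-r2, dist, cand$variant_id)][1]
}
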