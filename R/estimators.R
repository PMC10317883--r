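mr_result_row <- function(method, exposure, outcome, n_snps, estimate, se,
                          egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                          mean_F = NA_real_, steiger_filtered = FALSE) {
  z <- estimate / se
  data.frame(
    method = method, exposure = exposure, outcome = outcome, n_snps = n_snps,
    estimate = estimate, se = se,
    ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
    p = 2 * stats::pnorm(-abs(z)),
    egger_intercept = egger_intercept, egger_intercept_p = egger_intercept_p,
    mean_F = mean_F, steiger_filtered = steiger_filtered,
    stringsAsFactors = FALSE
  )
}

#' Inverse variance weighted MR estimate
#'
#' Weighted regression of the variant-outcome effects on the variant-exposure
#' effects through the origin, each variant weighted by the inverse variance
#' of its variant-outcome relationship: estimate
#' `sum(w bx by) / sum(w bx^2)` with `w = 1 / se_outcome^2`. The standard
#' error `1 / sqrt(sum(w bx^2))` is inflated by `sqrt(MSE)` when the weighted
#' residual mean square exceeds 1 (multiplicative random-effects guard); a
#' single variant reduces to the Wald ratio and is flagged.
#'
#' @param h A `harmonised_set` (single exposure).
#' @param exposure,outcome Labels carried into the result.
#' @return One-row MR result data frame (`method = "IVW"`).
#' @export
mr_ivw <- function(h, exposure = "exposure", outcome = "outcome") {
  k <- nrow(h)
  if (k < 1) stop("no harmonised variants")
  bx <- h$beta_exposure
  by <- h$beta_outcome
  if (all(bx == 0)) stop("all exposure betas are zero; estimate undefined")
  w <- 1 / h$se_outcome^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  if (k >= 2) {
    mse <- sum(w * (by - est * bx)^2) / (k - 1)
    se <- se * max(1, sqrt(mse))
  } else {
    warning("single-variant IVW reduces to a Wald ratio")
  }
  mr_result_row("IVW", exposure, outcome, k, est, se,
                mean_F = mean((bx / h$se_exposure)^2),
                steiger_filtered = isTRUE(attr(h, "steiger_filtered")))
}

#' MR-Egger regression
#'
#' Weighted least squares of the variant-outcome effects on the
#' variant-exposure effects WITH an intercept (weights inverse
#' outcome-variance), after flipping rows so all exposure betas are
#' non-negative. The slope is the pleiotropy-robust causal estimate; a
#' non-zero intercept indicates directional horizontal pleiotropy. Standard
#' errors carry the same multiplicative guard as [mr_ivw()].
#'
#' @inheritParams mr_ivw
#' @return One-row MR result data frame (`method = "Egger"`) with
#'   `egger_intercept` and `egger_intercept_p` filled in.
#' @export
mr_egger <- function(h, exposure = "exposure", outcome = "outcome") {
  k <- nrow(h)
  if (k < 3) stop("MR-Egger needs at least 3 variants")
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  bx <- h$beta_exposure * s
  by <- h$beta_outcome * s
  if (stats::var(bx) == 0) stop("degenerate exposure betas: collinear with the intercept")
  w <- 1 / h$se_outcome^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, X * w)
  XtWy <- crossprod(X, by * w)
  coef <- drop(solve(XtWX, XtWy))
  resid <- by - drop(X %*% coef)
  mse <- sum(w * resid^2) / (k - 2)
  V <- solve(XtWX) * max(1, mse)
  se <- sqrt(diag(V))
  icp_z <- coef["intercept"] / se["intercept"]
  mr_result_row("Egger", exposure, outcome, k, coef[["slope"]], se[["slope"]],
                egger_intercept = coef[["intercept"]],
                egger_intercept_p = 2 * stats::pnorm(-abs(icp_z)),
                mean_F = mean((bx / h$se_exposure)^2),
                steiger_filtered = isTRUE(attr(h, "steiger_filtered")))
}

#' Multivariable MR: direct effects of two exposures
#'
#' Weighted least squares of the variant-outcome effects on both
#' variant-exposure effect vectors without an intercept (weights inverse
#' outcome-variance). Each exposure's coefficient is its direct effect,
#' conditional on the genetic liability to the other exposure. Standard
#' errors come from the weighted normal equations with the multiplicative
#' guard of [mr_ivw()].
#'
#' @param h A `harmonised_set` from [harmonise_mvmr()] (columns
#'   `beta_exposure1`, `beta_exposure2`).
#' @param exposures Length-2 character vector of exposure labels.
#' @param outcome Outcome label.
#' @return Two-row MR result data frame (`method = "MVMR"`), one row per
#'   exposure.
#' @export
mr_mvmr <- function(h, exposures = c("exposure1", "exposure2"), outcome = "outcome") {
  k <- nrow(h)
  if (k < 3) stop("MVMR needs at least 3 variants (n_exposures + 1)")
  X <- cbind(h$beta_exposure1, h$beta_exposure2)
  zero_col <- colSums(X != 0) == 0
  if (all(zero_col)) stop("all exposure betas are zero; estimates undefined")
  if (any(zero_col)) {
    # a vanishing exposure decouples: the other exposure's normal equation is
    # exactly the univariable IVW on the same rows
    warning("exposure '", exposures[zero_col][1], "' has all-zero betas; ",
            "reporting NA for it and the univariable estimate for the other")
    live <- which(!zero_col)
    h1 <- h
    h1$beta_exposure <- X[, live]
    h1$se_exposure <- if (live == 1) h$se_exposure1 else h$se_exposure2
    uni <- mr_ivw(h1, exposures[live], outcome)
    uni$method <- "MVMR"
    na_row <- mr_result_row("MVMR", exposures[zero_col][1], outcome, k,
                            NA_real_, NA_real_,
                            steiger_filtered = isTRUE(attr(h, "steiger_filtered")))
    out <- if (live == 1) rbind(uni, na_row) else rbind(na_row, uni)
    rownames(out) <- NULL
    return(out)
  }
  if (qr(X)$rank < 2) stop("rank-deficient exposure beta matrix (collinear instruments)")
  w <- 1 / h$se_outcome^2
  XtWX <- crossprod(X, X * w)
  coef <- drop(solve(XtWX, crossprod(X, h$beta_outcome * w)))
  resid <- h$beta_outcome - drop(X %*% coef)
  mse <- sum(w * resid^2) / (k - 2)
  V <- solve(XtWX) * max(1, mse)
  se <- sqrt(diag(V))
  mf <- c(mean((h$beta_exposure1 / h$se_exposure1)^2),
          mean((h$beta_exposure2 / h$se_exposure2)^2))
  out <- rbind(
    mr_result_row("MVMR", exposures[1], outcome, k, coef[1], se[1], mean_F = mf[1],
                  steiger_filtered = isTRUE(attr(h, "steiger_filtered"))),
    mr_result_row("MVMR", exposures[2], outcome, k, coef[2], se[2], mean_F = mf[2],
                  steiger_filtered = isTRUE(attr(h, "steiger_filtered")))
  )
  rownames(out) <- NULL
  out
}

#' Steiger directionality filter
#'
#' Removes variants whose variance explained in the outcome,
#' `2 * beta_outcome^2 * eaf * (1 - eaf)`, is at least that explained in the
#' exposure — i.e. retains rows with `|beta_exposure| > |beta_outcome|` when
#' both traits are on comparable standardised scales (the boundary case of
#' equality is removed). Removed rows are logged in the `steiger_removed`
#' attribute with both variance-explained values.
#'
#' @param h A `harmonised_set`; for a multi-exposure set the larger of the
#'   two exposure variances explained is compared against the outcome.
#' @param exposure_beta Optional column name overriding which exposure beta
#'   is compared.
#' @return The filtered `harmonised_set` (possibly empty, with a warning),
#'   flagged `steiger_filtered`.
#' @export
steiger_filter <- function(h, exposure_beta = NULL) {
  vx <- if (!is.null(exposure_beta)) {
    variance_explained(h[[exposure_beta]], h$eaf)
  } else if ("beta_exposure" %in% names(h)) {
    variance_explained(h$beta_exposure, h$eaf)
  } else {
    # multi-exposure set: a variant survives if it is a stronger proxy for
    # either exposure than for the outcome
    pmax(variance_explained(h$beta_exposure1, h$eaf),
         variance_explained(h$beta_exposure2, h$eaf))
  }
  vy <- variance_explained(h$beta_outcome, h$eaf)
  keep <- vx > vy
  removed <- data.frame(
    variant_id = h$variant_id[!keep],
    var_exp_exposure = vx[!keep],
    var_exp_outcome = vy[!keep],
    stringsAsFactors = FALSE
  )
  out <- h[keep, , drop = FALSE]
  if (!nrow(out)) warning("Steiger filtering removed every variant")
  attr(out, "dropped") <- attr(h, "dropped")
  attr(out, "steiger_removed") <- removed
  attr(out, "steiger_filtered") <- TRUE
  class(out) <- class(h)
  out
}

#' Fixed-effect inverse-variance meta-analysis of MR results
#'
#' Pools estimates under the assumption of one common effect across studies:
#' pooled estimate `sum(est / se^2) / sum(1 / se^2)`, pooled standard error
#' `1 / sqrt(sum(1 / se^2))`. Binary-outcome results are pooled on the
#' log-odds scale (exponentiate only for reporting). All inputs must share
#' method and exposure; a single input is passed through with a warning.
#'
#' @param results Data frame of MR result rows (stacked [mr_ivw()] etc.).
#' @param outcome Label for the pooled outcome.
#' @return One-row MR result data frame with `n_snps` the median of the
#'   inputs' variant counts.
#' @export
fixed_effect_meta <- function(results, outcome = "meta") {
  if (!nrow(results)) stop("no results to pool")
  if (length(unique(results$method)) > 1 || length(unique(results$exposure)) > 1) {
    stop("pooling requires a single method and exposure on one scale")
  }
  if (nrow(results) == 1) {
    warning("single result: pass-through, nothing to pool")
    out <- results
    out$outcome <- outcome
    return(out)
  }
  w <- 1 / results$se^2
  est <- sum(w * results$estimate) / sum(w)
  se <- 1 / sqrt(sum(w))
  mr_result_row(results$method[1], results$exposure[1], outcome,
                stats::median(results$n_snps), est, se,
                mean_F = mean(results$mean_F),
                steiger_filtered = all(results$steiger_filtered))
}
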