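#' Reference distribution for the reconstructed childhood phenotype
#'
#' The anchored assignment draws childhood values from a reference
#' distribution describing the measured trait in an external birth cohort.
#' Supported families: `normal` (location = mean, scale = SD), `lognormal`
#' (location = meanlog, scale = sdlog), and `empirical` (a strictly monotone
#' probability/value quantile grid, interpolated linearly and clamped at the
#' ends).
#'
#' The default is a documented placeholder for age-11 BMI in a mid-century
#' British birth cohort: normal with mean 17.8 and SD 2.8 kg/m^2.
#'
#' @param family `"normal"`, `"lognormal"` or `"empirical"`.
#' @param location,scale Parameters for the parametric families; `scale > 0`.
#' @param quantiles For `empirical`: data frame or list with `probability` and
#'   `value`, both strictly increasing.
#' @return Object of class `reference_distribution`.
#' @export
reference_distribution <- function(family = c("normal", "lognormal", "empirical"),
                                   location = 17.8, scale = 2.8, quantiles = NULL) {
  family <- match.arg(family)
  if (family == "empirical") {
    q <- as.data.frame(quantiles)
    if (!all(c("probability", "value") %in% names(q))) {
      stop("empirical reference needs 'probability' and 'value'")
    }
    if (any(diff(q$probability) <= 0) || any(diff(q$value) <= 0)) {
      stop("empirical quantile grid must be strictly increasing in both coordinates")
    }
    if (any(q$probability < 0 | q$probability > 1)) stop("probabilities outside [0, 1]")
  } else {
    if (scale <= 0) stop("scale must be > 0")
    q <- NULL
  }
  structure(list(family = family, location = location, scale = scale, quantiles = q),
            class = "reference_distribution")
}

#' Quantile function of a reference distribution
#'
#' @param reference A [reference_distribution()].
#' @param p Probabilities in `[0, 1]`.
#' @return Quantiles in phenotype units.
#' @export
ref_quantile <- function(reference, p) {
  switch(reference$family,
    normal = stats::qnorm(p, reference$location, reference$scale),
    lognormal = stats::qlnorm(p, reference$location, reference$scale),
    empirical = stats::approx(reference$quantiles$probability, reference$quantiles$value,
                              xout = p, rule = 2)$y
  )
}

#' Assign continuous values to recall categories by anchored sub-sampling
#'
#' The probability axis is partitioned at the observed category proportions
#' (`thinner` takes the lowest segment, `plumper` the highest); each
#' individual receives `Q(u)` where `u` is uniform on their category's
#' segment of the reference quantile function `Q`. Over the whole sample the
#' assigned values therefore reproduce the reference distribution, while the
#' ordering across categories preserves the anchor.
#'
#' @param categories Factor/character vector with values in
#'   `thinner`, `same`, `plumper`.
#' @param reference A [reference_distribution()].
#' @param seed Integer seed.
#' @return Numeric vector of assigned phenotype values.
#' @export
assign_continuous <- function(categories, reference, seed = 1L) {
  if (!length(categories)) stop("empty category vector")
  lev <- c("thinner", "same", "plumper")
  cats <- as.character(categories)
  if (!all(cats %in% lev)) {
    stop("unrecognised categories: ", paste(unique(setdiff(cats, lev)), collapse = ", "))
  }
  n <- length(cats)
  prop <- c(mean(cats == "thinner"), mean(cats == "same"), mean(cats == "plumper"))
  lower <- c(0, prop[1], prop[1] + prop[2])
  upper <- c(prop[1], prop[1] + prop[2], 1)
  idx <- match(cats, lev)
  old <- .Random.seed_exists()
  set.seed(seed)
  u <- lower[idx] + stats::runif(n) * (upper[idx] - lower[idx])
  .restore_seed(old)
  ref_quantile(reference, u)
}

#' Rank-based inverse normal transformation (Blom offset)
#'
#' Maps values to `qnorm((rank - 3/8) / (n + 1/4))` with ties given the
#' average rank — the conventional phenotype standardisation before a GWAS.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Vector of normal scores, same order as the input.
#' @export
rank_inverse_normalise <- function(values) {
  if (length(values) < 2 || length(unique(values)) < 2) {
    stop("rank inverse normalisation needs at least two distinct values")
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Residualise a phenotype on covariates by OLS
#'
#' Fits `values ~ intercept + covariates` and returns the residuals. The
#' design must be full rank after adding the intercept; otherwise the
#' offending columns are reported.
#'
#' @param values Numeric vector.
#' @param covariates Data frame, row-aligned with `values`; factors are
#'   expanded to dummies.
#' @return Residual vector.
#' @export
residualise <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(values)) stop("covariates not row-aligned with values")
  X <- stats::model.matrix(~., data = covariates)
  # constant columns are absorbed into the intercept, not a rank failure
  const <- apply(X[, -1, drop = FALSE], 2, function(col) length(unique(col)) == 1)
  X <- X[, c(TRUE, !const), drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qx, values)
}
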