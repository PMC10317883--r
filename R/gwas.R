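#' Per-variant association scan
#'
#' For a continuous phenotype each variant is tested with ordinary least
#' squares, `phenotype ~ intercept + dosage + covariates`; the covariates are
#' projected out once (Frisch-Waugh-Lovell), which gives slope, standard error
#' and residual degrees of freedom identical to the per-variant full fit. For
#' a binary phenotype each variant is tested with per-variant logistic
#' regression and Wald statistics, returning log-odds effects.
#'
#' Monomorphic variants yield an `NA` row with a warning. Reported
#' effect-allele frequencies are empirical in the tested cohort.
#'
#' @param genotypes Dosage matrix (individuals x variants).
#' @param phenotype Numeric vector (0/1 for `family = "binomial"`).
#' @param covariates Optional data frame of covariates.
#' @param variants Optional variant table; when given, identity/location and
#'   allele columns are carried into the result.
#' @param trait_label Label stored in the `trait` column.
#' @param family `"gaussian"` or `"binomial"`.
#' @return Data frame of per-variant association statistics with columns
#'   `variant_id`, (`chromosome`, `position`, `effect_allele`, `other_allele`
#'   when `variants` is given), `eaf`, `beta`, `se`, `p_value`, `n`, `trait`.
#' @export
run_gwas <- function(genotypes, phenotype, covariates = NULL, variants = NULL,
                     trait_label = "trait", family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  n <- length(phenotype)
  if (nrow(genotypes) != n) stop("genotype/phenotype dimensions disagree")
  eaf <- colMeans(genotypes) / 2
  mono <- eaf <= 0 | eaf >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) reported as NA")
  }

  if (family == "gaussian") {
    if (is.null(covariates)) {
      # intercept-only: centred simple regression without copying the matrix
      gm <- colMeans(genotypes)
      y_t <- phenotype - mean(phenotype)
      sxx <- colSums(genotypes^2) - n * gm^2
      sxy <- drop(crossprod(genotypes, y_t))
      syy <- sum(y_t^2)
      df <- n - 2L
    } else {
      covariates <- as.data.frame(covariates)
      W <- stats::model.matrix(~., data = covariates)
      qw <- qr(W)
      if (qw$rank < ncol(W)) {
        bad <- colnames(W)[qw$pivot[(qw$rank + 1):ncol(W)]]
        stop("rank-deficient covariates: ", paste(bad, collapse = ", "))
      }
      y_t <- qr.resid(qw, phenotype)
      G_t <- qr.resid(qw, genotypes)
      sxx <- colSums(G_t^2)
      sxy <- drop(crossprod(G_t, y_t))
      syy <- sum(y_t^2)
      df <- n - ncol(W) - 1L
    }
    beta <- sxy / sxx
    rss <- syy - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    beta[mono] <- NA_real_
    se[mono] <- NA_real_
  } else {
    if (!all(phenotype %in% c(0, 1))) stop("binomial family expects a 0/1 phenotype")
    X0 <- if (is.null(covariates)) {
      matrix(1, n, 1)
    } else {
      stats::model.matrix(~., data = as.data.frame(covariates))
    }
    beta <- se <- rep(NA_real_, ncol(genotypes))
    for (j in seq_len(ncol(genotypes))) {
      if (mono[j]) next
      fit <- stats::glm.fit(cbind(X0, dose = genotypes[, j]), phenotype,
                            family = stats::binomial())
      cf <- length(fit$coefficients)
      # Wald se from the weighted information matrix at convergence
      Xw <- cbind(X0, genotypes[, j]) * sqrt(fit$weights)
      V <- chol2inv(chol(crossprod(Xw)))
      beta[j] <- fit$coefficients[cf]
      se[j] <- sqrt(V[cf, cf])
    }
  }

  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    variant_id = colnames(genotypes),
    eaf = eaf,
    beta = beta,
    se = se,
    p_value = p,
    n = n,
    trait = trait_label,
    stringsAsFactors = FALSE
  )
  if (!is.null(variants)) {
    keep <- c("variant_id", "chromosome", "position", "effect_allele", "other_allele")
    out <- merge(variants[, keep], out, by = "variant_id", sort = FALSE)
    out <- out[match(colnames(genotypes), out$variant_id), ]
    rownames(out) <- NULL
  }
  out
}

#' Pairwise r-squared accessor from a genotype panel
#'
#' Squared Pearson correlation between dosage columns, with pairs on
#' different chromosomes set to 0 (as a clumping reference panel treats
#' them). Degenerate (monomorphic) columns get r-squared 0.
#'
#' @param genotypes Dosage matrix with variant ids as column names.
#' @param variants Variant table giving each id's chromosome.
#' @return Symmetric matrix of r-squared values with variant-id dimnames.
#' @export
ld_r2 <- function(genotypes, variants) {
  r <- panel_cor(genotypes)
  r2 <- r^2
  chrom <- variants$chromosome[match(colnames(genotypes), variants$variant_id)]
  same_chr <- outer(chrom, chrom, "==")
  r2[!same_chr] <- 0
  diag(r2) <- 1
  r2
}

# Pearson correlation via one crossproduct (fast on tall dosage matrices);
# degenerate columns get correlation 0 off the diagonal.
panel_cor <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  cp <- crossprod(xc)
  s <- sqrt(diag(cp))
  s[s == 0] <- Inf
  r <- cp / tcrossprod(s)
  diag(r) <- 1
  r
}
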