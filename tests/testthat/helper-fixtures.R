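# Shared fixtures: small, fast synthetic designs used across test files.

# Desk-scale architecture with per-variant effects strong enough that a
# cohort of a few thousand still yields genome-wide-significant instruments.
small_arch <- function(n_child = 20L, n_adult = 30L, n_shared = 10L,
                       effect_sd = 0.195, ld_rho = 0.3, block = 5L) {
  genetic_architecture(
    n_child_specific = n_child, n_adult_specific = n_adult, n_shared = n_shared,
    effect_sd_child = effect_sd, effect_sd_adult = effect_sd,
    effect_sd_shared = effect_sd, ld_block_size = block, ld_rho = ld_rho
  )
}

small_config <- function(n = 2000L, outcomes = NULL, use_recall = TRUE, ...) {
  if (is.null(outcomes)) {
    outcomes <- list(trait = list(type = "continuous", theta_child = -0.1,
                                  theta_adult = 0.3))
  }
  default_config(
    cohorts = list(n_exposure = n, n_outcome = n, n_validation = 0L),
    architecture = list(
      n_child_specific = 20L, n_adult_specific = 30L, n_shared = 10L,
      effect_sd_child = 0.195, effect_sd_adult = 0.195, effect_sd_shared = 0.195,
      shared_adult_scale = 1 / sqrt(2), ld_block_size = 5L, ld_rho = 0.3
    ),
    construction = list(use_recall = use_recall,
                        reference = list(family = "normal", location = 17.8, scale = 2.8)),
    outcomes = outcomes,
    ...
  )
}

# A deterministic harmonised set for estimator tests.
random_harmonised <- function(k, seed, two_exposures = FALSE) {
  set.seed(seed)
  h <- data.frame(
    variant_id = sprintf("rs%03d", seq_len(k)),
    chromosome = 1L, position = seq_len(k) * 1e5,
    effect_allele = "A", other_allele = "G",
    eaf = runif(k, 0.1, 0.9),
    beta_exposure = rnorm(k, 0, 0.1),
    se_exposure = runif(k, 0.005, 0.02),
    beta_outcome = rnorm(k, 0, 0.05),
    se_outcome = runif(k, 0.005, 0.03),
    flipped = FALSE, proxy_used = FALSE,
    stringsAsFactors = FALSE
  )
  if (two_exposures) {
    names(h)[names(h) == "beta_exposure"] <- "beta_exposure1"
    names(h)[names(h) == "se_exposure"] <- "se_exposure1"
    h$beta_exposure2 <- rnorm(k, 0, 0.1)
    h$se_exposure2 <- runif(k, 0.005, 0.02)
  }
  class(h) <- c("harmonised_set", "data.frame")
  h
}

# Minimal association table for harmonisation tests.
assoc_row <- function(id, ea, oa, eaf, beta, se = 0.01, chrom = 1L, pos = 1000L) {
  data.frame(variant_id = id, chromosome = chrom, position = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, p_value = 2 * pnorm(-abs(beta / se)),
             n = 10000L, trait = "t", stringsAsFactors = FALSE)
}

# Independent weighted-least-squares oracle: explicit normal equations with
# the documented multiplicative residual guard. Used to cross-check the
# estimators; shares no code with the implementation.
wls_oracle <- function(X, y, w, guard_df) {
  A <- t(X * w) %*% X
  b <- t(X * w) %*% y
  coef <- solve(A) %*% b
  resid <- y - X %*% coef
  mse <- sum(w * resid^2) / guard_df
  V <- solve(A) * max(1, mse)
  list(coef = drop(coef), se = sqrt(diag(V)))
}
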