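#' Canonical simulation experiments
#'
#' `recovery_config()` is the parameter-recovery experiment: the default
#' architecture and cohort sizes with one continuous outcome carrying the
#' given direct effects, analysed on the directly simulated exposures (the
#' recall construction changes the exposure scale, so truth recovery is
#' defined on the simulated scale; construction fidelity is assessed
#' separately). `attenuation_config()` is the path-tracing experiment: no
#' shared variants (so childhood instruments reach the outcome only through
#' the two exposures), `theta_child = 0`, and the childhood phenotype's only
#' route to the outcome the `phi * theta_adult` path — univariable childhood
#' IVW then converges to `theta_child + phi * theta_adult` while the MVMR
#' childhood direct effect converges to 0.
#'
#' @param theta_child,theta_adult Direct effects of the single continuous
#'   outcome.
#' @param phi Childhood-to-adulthood causal path.
#' @return A configuration list for [run_pipeline()]/[replicate_study()].
#' @export
recovery_config <- function(theta_child = -0.05, theta_adult = 0.15, phi = 0.3) {
  default_config(
    cohorts = list(n_exposure = 20000L, n_outcome = 20000L, n_validation = 0L),
    truth = list(phi = phi, confounder = list(child = 0.15, adult = 0.15, outcome = 0.15)),
    construction = list(use_recall = FALSE,
                        reference = list(family = "normal", location = 17.8, scale = 2.8)),
    mr = list(run_egger = FALSE, run_steiger = FALSE, egger_flag_p = 0.01,
              proxy_r2_min = 0.8, proxy_window_kb = 250,
              outcome_missing_rate = 0.02, randomise_orientation = TRUE),
    outcomes = list(outcome = list(type = "continuous", theta_child = theta_child,
                                   theta_adult = theta_adult))
  )
}

#' @rdname recovery_config
#' @export
attenuation_config <- function(phi = 0.5, theta_adult = 0.2) {
  cfg <- recovery_config(theta_child = 0, theta_adult = theta_adult, phi = phi)
  cfg$architecture$n_shared <- 0L
  cfg
}

#' Intercept test size of MR-Egger under a no-pleiotropy null
#'
#' Summary-statistic simulation: per replicate, true exposure effects are
#' drawn from a zero-mean normal, measured with sampling error, and the
#' variant-outcome effects are generated with zero intercept
#' (`by = theta * bx + noise`). The rejection rate of the Egger intercept
#' test at `alpha` estimates the test's type-I error.
#'
#' @param n_variants Instruments per replicate.
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @param theta True causal slope.
#' @param bx_sd SD of the true exposure effects.
#' @param se_x,se_y Sampling SDs of the measured exposure/outcome effects.
#' @param alpha Test level.
#' @return List with `rejection_rate`, `mean_intercept`, `n_replicates`.
#' @export
egger_null_rejection <- function(n_variants = 50L, n_replicates = 200L, seed = 1L,
                                 theta = 0.2, bx_sd = 0.1, se_x = 0.01,
                                 se_y = 0.02, alpha = 0.05) {
  old <- .Random.seed_exists()
  set.seed(seed)
  pvals <- icpt <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    bx <- stats::rnorm(n_variants, 0, bx_sd)
    bxh <- bx + stats::rnorm(n_variants, 0, se_x)
    byh <- theta * bx + stats::rnorm(n_variants, 0, se_y)
    h <- data.frame(
      variant_id = sprintf("rs%04d", seq_len(n_variants)),
      eaf = 0.5, beta_exposure = bxh, se_exposure = se_x,
      beta_outcome = byh, se_outcome = se_y,
      flipped = FALSE, proxy_used = FALSE, stringsAsFactors = FALSE
    )
    res <- mr_egger(h)
    pvals[r] <- res$egger_intercept_p
    icpt[r] <- res$egger_intercept
  }
  .restore_seed(old)
  list(rejection_rate = mean(pvals < alpha), mean_intercept = mean(icpt),
       n_replicates = n_replicates)
}

#' Replicate a simulated study and measure estimator performance
#'
#' Runs [run_pipeline()] over independent seeds and aggregates each
#' method/exposure/outcome cell against the configured truth: Monte-Carlo
#' mean, bias, empirical SE (the standard deviation of the estimates across
#' replicates), the Monte-Carlo standard error of the mean, 95%
#' confidence-interval coverage, and the rejection rate of the Egger
#' intercept test at the 5% level.
#'
#' Reference values: the MVMR rows are compared against the configured direct
#' effects; univariable childhood rows against the path-tracing total
#' `theta_child + phi * theta_adult` (exact when childhood instruments reach
#' the outcome only through the two exposures, i.e. with no shared variants
#' carrying direct adulthood effects); univariable adulthood rows against
#' `theta_adult` (exact when `theta_child = 0`).
#'
#' Replicate failures are caught, counted and reported; the run continues.
#'
#' @param config Configuration from [default_config()].
#' @param n_replicates Number of replicates (`>= 1`; coverage claims need
#'   at least 50).
#' @param seed Master seed; replicate `i` uses `sub_seed(seed, i)`.
#' @param quiet Suppress per-replicate progress.
#' @return List with `summary` (one row per method/exposure/outcome/filter),
#'   `egger` (intercept-test rejection rates), `estimates` (all raw result
#'   rows with a `replicate` column), `n_replicates`, `n_failed`.
#' @export
replicate_study <- function(config = default_config(), n_replicates = 200L,
                            seed = 1L, quiet = TRUE) {
  if (n_replicates < 1) stop("insufficient replicates")
  rows <- vector("list", n_replicates)
  failed <- 0L
  for (i in seq_len(n_replicates)) {
    res <- tryCatch(
      run_pipeline(config, seed = sub_seed(seed, i), quiet = TRUE),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- failed + 1L
      if (!quiet) message(sprintf("replicate %d failed: %s", i, conditionMessage(res)))
      next
    }
    r <- res$results
    r$replicate <- i
    rows[[i]] <- r
    if (!quiet && i %% 25 == 0) message(sprintf("replicate %d / %d", i, n_replicates))
  }
  est <- do.call(rbind, rows)
  if (is.null(est) || !nrow(est)) stop("every replicate failed")

  phi <- config$truth$phi
  ref_value <- function(method, exposure, outcome) {
    base <- sub("_study[0-9]+$", "", outcome)
    os <- config$outcomes[[base]]
    if (is.null(os)) return(NA_real_)
    if (method == "MVMR") {
      if (exposure == "childhood") os$theta_child else os$theta_adult
    } else if (exposure == "childhood") {
      os$theta_child + phi * os$theta_adult
    } else {
      os$theta_adult
    }
  }

  key <- unique(est[, c("method", "exposure", "outcome", "steiger_filtered")])
  summary <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sub <- est[est$method == key$method[i] & est$exposure == key$exposure[i] &
                 est$outcome == key$outcome[i] &
                 est$steiger_filtered == key$steiger_filtered[i], ]
    ref <- ref_value(key$method[i], key$exposure[i], key$outcome[i])
    data.frame(
      method = key$method[i], exposure = key$exposure[i], outcome = key$outcome[i],
      steiger_filtered = key$steiger_filtered[i],
      n = nrow(sub),
      reference = ref,
      mean_estimate = mean(sub$estimate),
      bias = mean(sub$estimate) - ref,
      empirical_se = stats::sd(sub$estimate),
      se_of_mean = stats::sd(sub$estimate) / sqrt(nrow(sub)),
      mean_model_se = mean(sub$se),
      coverage = mean(sub$ci_low <= ref & ref <= sub$ci_high),
      mean_n_snps = mean(sub$n_snps),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summary) <- NULL

  egger <- NULL
  eg <- est[est$method == "Egger", ]
  if (nrow(eg)) {
    ek <- unique(eg[, c("exposure", "outcome")])
    egger <- do.call(rbind, lapply(seq_len(nrow(ek)), function(i) {
      sub <- eg[eg$exposure == ek$exposure[i] & eg$outcome == ek$outcome[i], ]
      data.frame(exposure = ek$exposure[i], outcome = ek$outcome[i],
                 n = nrow(sub),
                 rejection_rate_05 = mean(sub$egger_intercept_p < 0.05),
                 mean_intercept = mean(sub$egger_intercept),
                 stringsAsFactors = FALSE)
    }))
    rownames(egger) <- NULL
  }

  list(summary = summary, egger = egger, estimates = est,
       n_replicates = n_replicates, n_failed = failed)
}
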