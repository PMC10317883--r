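test_that("harmonisation keeps aligned rows and flips swapped alleles", {
  exp <- assoc_row("rs1", "A", "G", 0.3, 0.12)
  out_same <- assoc_row("rs1", "A", "G", 0.31, 0.2)
  h <- harmonise(exp, out_same)
  expect_equal(h$beta_outcome, 0.2)
  expect_false(h$flipped)

  out_swap <- assoc_row("rs1", "G", "A", 0.69, 0.2)
  h2 <- harmonise(exp, out_swap)
  expect_equal(h2$beta_outcome, -0.2)
  expect_true(h2$flipped)
  expect_equal(h2$eaf, 0.3)
})

test_that("ambiguous palindromes and mismatches are dropped with reasons", {
  exp <- rbind(assoc_row("rs1", "A", "T", 0.5, 0.1),
               assoc_row("rs2", "C", "G", 0.2, 0.1),
               assoc_row("rs3", "A", "G", 0.3, 0.1),
               assoc_row("rs4", "A", "C", 0.3, 0.1))
  out <- rbind(assoc_row("rs1", "A", "T", 0.5, 0.2),    # palindrome at 0.50
               assoc_row("rs2", "C", "G", 0.21, 0.2),   # palindrome, informative
               assoc_row("rs3", "A", "C", 0.3, 0.2),    # allele mismatch
               assoc_row("rs4", "A", "C", 0.6, 0.2))    # eaf mismatch
  h <- harmonise(exp, out)
  expect_equal(h$variant_id, "rs2")
  dropped <- attr(h, "dropped")
  expect_equal(dropped$reason[dropped$variant_id == "rs1"], "ambiguous_palindrome")
  expect_equal(dropped$reason[dropped$variant_id == "rs3"], "allele_mismatch")
  expect_equal(dropped$reason[dropped$variant_id == "rs4"], "eaf_mismatch")
  expect_error(harmonise(rbind(exp, exp[1, ]), out), "duplicated")
})

test_that("harmonisation is involutive on already-harmonised tables", {
  exp <- rbind(assoc_row("rs1", "A", "G", 0.3, 0.12),
               assoc_row("rs2", "C", "A", 0.6, -0.08, pos = 5000L))
  out <- rbind(assoc_row("rs1", "G", "A", 0.72, 0.2),
               assoc_row("rs2", "C", "A", 0.63, 0.05, pos = 5000L))
  h1 <- harmonise(exp, out)
  # rebuild outcome-shaped stats from the harmonised set and re-harmonise
  out2 <- h1
  out2$beta <- h1$beta_outcome
  out2$se <- h1$se_outcome
  h2 <- harmonise(exp, out2[, c("variant_id", "chromosome", "position",
                                "effect_allele", "other_allele", "eaf", "beta", "se")])
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf, h1$eaf)
  expect_false(any(h2$flipped))
})

test_that("proxy search is a constrained argmax with a strict threshold", {
  ids <- c("t", "p1", "p2", "p3")
  v <- data.frame(variant_id = ids, chromosome = 1L,
                  position = c(1e6, 1.05e6, 1.1e6, 1.3e6))
  ld <- matrix(0, 4, 4, dimnames = list(ids, ids))
  diag(ld) <- 1
  ld["t", c("p1", "p2", "p3")] <- ld[c("p1", "p2", "p3"), "t"] <- c(0.85, 0.9, 0.95)
  # the 0.95 candidate is 300 kb away: the 0.9 one wins
  expect_equal(find_proxy("t", c("p1", "p2", "p3"), ld, v), "p2")
  # self-proxy when the target is available
  expect_equal(find_proxy("t", ids, ld, v), "t")
  # r2 = 0.79 fails the strict bound
  ld["t", "p1"] <- ld["p1", "t"] <- 0.79
  expect_true(is.na(find_proxy("t", "p1", ld, v)))
})

test_that("IVW reduces to the Wald ratio and the weighted mean", {
  h1 <- random_harmonised(1, 1)
  h1$beta_exposure <- 0.1
  h1$beta_outcome <- 0.05
  expect_warning(res <- mr_ivw(h1), "Wald")
  expect_equal(res$estimate, 0.5)

  h2 <- random_harmonised(10, 2)
  h2$beta_exposure <- 1
  h2$se_outcome <- 0.01
  res2 <- mr_ivw(h2)
  expect_equal(res2$estimate, mean(h2$beta_outcome))

  h0 <- random_harmonised(5, 3)
  h0$beta_exposure <- 0
  expect_error(mr_ivw(h0), "zero")
})

test_that("IVW matches the brute-force weighted solve", {
  for (seed in 1:5) {
    h <- random_harmonised(20, seed)
    res <- mr_ivw(h)
    or <- wls_oracle(cbind(h$beta_exposure), h$beta_outcome, 1 / h$se_outcome^2,
                     guard_df = nrow(h) - 1)
    expect_equal(res$estimate, or$coef, tolerance = 1e-10)
    expect_equal(res$se, or$se, tolerance = 1e-10)
    expect_equal(res$ci_low, res$estimate - 1.96 * res$se)
    expect_equal(res$p, 2 * pnorm(-abs(res$estimate / res$se)))
  }
})

test_that("Egger fits slope and intercept and rejects degenerate input", {
  expect_error(mr_egger(random_harmonised(2, 4)), "at least 3")
  h <- random_harmonised(15, 5)
  h$beta_exposure <- abs(h$beta_exposure)
  h$beta_outcome <- 0.02 + 0.4 * h$beta_exposure
  res <- mr_egger(h)
  expect_equal(res$estimate, 0.4, tolerance = 1e-8)
  expect_equal(res$egger_intercept, 0.02, tolerance = 1e-8)

  hdeg <- random_harmonised(5, 6)
  hdeg$beta_exposure <- 0.1
  expect_error(mr_egger(hdeg), "degenerate")
})

test_that("Egger orientation flips rows to non-negative exposure betas", {
  h <- random_harmonised(12, 7)
  res <- mr_egger(h)
  h_flip <- h
  h_flip$beta_exposure <- -h$beta_exposure
  h_flip$beta_outcome <- -h$beta_outcome
  expect_equal(mr_egger(h_flip)$estimate, res$estimate)
  expect_equal(mr_egger(h_flip)$egger_intercept, res$egger_intercept)
  # oracle on the flipped scale
  s <- ifelse(h$beta_exposure < 0, -1, 1)
  or <- wls_oracle(cbind(1, h$beta_exposure * s), h$beta_outcome * s,
                   1 / h$se_outcome^2, guard_df = nrow(h) - 2)
  expect_equal(res$estimate, or$coef[2], tolerance = 1e-10)
  expect_equal(res$se, or$se[2], tolerance = 1e-10)
  expect_equal(res$egger_intercept, or$coef[1], tolerance = 1e-10)
})

test_that("MVMR matches the two-column weighted solve and nests IVW", {
  for (seed in 8:10) {
    h <- random_harmonised(25, seed, two_exposures = TRUE)
    res <- mr_mvmr(h)
    or <- wls_oracle(cbind(h$beta_exposure1, h$beta_exposure2), h$beta_outcome,
                     1 / h$se_outcome^2, guard_df = nrow(h) - 2)
    expect_equal(res$estimate, unname(or$coef), tolerance = 1e-10)
    expect_equal(res$se, unname(or$se), tolerance = 1e-10)
  }
  # null second exposure: childhood estimate collapses to univariable IVW
  h <- random_harmonised(25, 11, two_exposures = TRUE)
  h$beta_exposure2 <- 0
  expect_warning(res <- mr_mvmr(h), "all-zero")
  h_uni <- h
  names(h_uni)[names(h_uni) == "beta_exposure1"] <- "beta_exposure"
  names(h_uni)[names(h_uni) == "se_exposure1"] <- "se_exposure"
  expect_equal(res$estimate[1], mr_ivw(h_uni)$estimate)
  expect_true(is.na(res$estimate[2]))
  # perfectly collinear exposures are rejected
  h2 <- random_harmonised(10, 12, two_exposures = TRUE)
  h2$beta_exposure2 <- 2 * h2$beta_exposure1
  expect_error(mr_mvmr(h2), "rank-deficient")
  expect_error(mr_mvmr(random_harmonised(2, 13, two_exposures = TRUE)), "at least 3")
})

test_that("Steiger filtering is a strict, idempotent subset", {
  h <- random_harmonised(3, 14)
  h$beta_exposure <- c(0.1, 0.2, 0.15)
  h$beta_outcome <- c(0.2, 0.1, 0.15)
  hf <- steiger_filter(h)
  expect_equal(hf$variant_id, "rs002")    # |bx| > |by| strictly; ties removed
  expect_true(all(hf$variant_id %in% h$variant_id))
  expect_equal(steiger_filter(hf)$variant_id, hf$variant_id)   # idempotent
  expect_true(attr(hf, "steiger_filtered"))
  removed <- attr(hf, "steiger_removed")
  expect_setequal(removed$variant_id, c("rs001", "rs003"))
  expect_true(all(c("var_exp_exposure", "var_exp_outcome") %in% names(removed)))
  h_all <- h
  h_all$beta_outcome <- h$beta_exposure * 2
  expect_warning(steiger_filter(h_all), "every variant")
})

test_that("fixed-effect pooling follows inverse-variance arithmetic", {
  r1 <- lifecourseMR:::mr_result_row("IVW", "childhood", "s1", 10, 0.3, 0.1)
  r2 <- lifecourseMR:::mr_result_row("IVW", "childhood", "s2", 12, 0.3, 0.1)
  pooled <- fixed_effect_meta(rbind(r1, r2), outcome = "meta")
  expect_equal(pooled$estimate, 0.3)
  expect_equal(pooled$se, 0.1 / sqrt(2))

  r3 <- lifecourseMR:::mr_result_row("IVW", "childhood", "s1", 10, 0, 1)
  r4 <- lifecourseMR:::mr_result_row("IVW", "childhood", "s2", 12, 0.4, 1 / sqrt(3))
  expect_equal(fixed_effect_meta(rbind(r3, r4))$estimate, 0.3)

  expect_warning(single <- fixed_effect_meta(r1, outcome = "m"), "single")
  expect_equal(single$estimate, 0.3)
  r5 <- r2
  r5$method <- "Egger"
  expect_error(fixed_effect_meta(rbind(r1, r5)), "single method")
})

test_that("pooling minimises the weighted sum of squares and matches metafor", {
  set.seed(15)
  k <- 6
  ests <- rnorm(k, 0.2, 0.1)
  ses <- runif(k, 0.05, 0.2)
  rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    lifecourseMR:::mr_result_row("IVW", "childhood", paste0("s", i), 10, ests[i], ses[i])
  }))
  pooled <- fixed_effect_meta(rows)
  # brute-force oracle: minimise sum((est - mu)^2 / se^2) over mu
  mu_opt <- stats::optimize(function(mu) sum((ests - mu)^2 / ses^2),
                            interval = range(ests))$minimum
  expect_equal(pooled$estimate, mu_opt, tolerance = 1e-6)
  if (requireNamespace("metafor", quietly = TRUE)) {
    fe <- metafor::rma(yi = ests, sei = ses, method = "FE")
    expect_equal(pooled$estimate, as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(pooled$se, fe$se, tolerance = 1e-10)
  }
})
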