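test_that("a perfect linear signal is recovered exactly", {
  arch <- small_arch(ld_rho = 0)
  v <- variant_panel(arch, 1)[1:5, ]
  G <- simulate_genotypes(200, v, arch, 1)
  gw <- run_gwas(G, 2 * G[, 3], trait_label = "x")
  expect_equal(gw$beta[3], 2, tolerance = 1e-10)
  expect_lt(gw$se[3], 1e-8)
})

test_that("the association scan equals a per-variant least-squares fit", {
  arch <- small_arch(ld_rho = 0.3)
  v <- variant_panel(arch, 2)[1:8, ]
  set.seed(2)
  G <- simulate_genotypes(400, v, arch, 2)
  y <- rnorm(400) + 0.1 * G[, 1]
  cov <- data.frame(sex = rbinom(400, 1, 0.5), age = rnorm(400))
  gw0 <- run_gwas(G, y, trait_label = "x")
  gwc <- run_gwas(G, y, covariates = cov, trait_label = "x")
  for (j in c(1, 4, 8)) {
    f0 <- summary(stats::lm(y ~ G[, j]))$coefficients
    expect_equal(gw0$beta[j], f0[2, 1], tolerance = 1e-10)
    expect_equal(gw0$se[j], f0[2, 2], tolerance = 1e-10)
    fc <- summary(stats::lm(y ~ G[, j] + sex + age, data = cov))$coefficients
    expect_equal(gwc$beta[j], fc[2, 1], tolerance = 1e-10)
    expect_equal(gwc$se[j], fc[2, 2], tolerance = 1e-10)
  }
})

test_that("logistic scan matches glm per variant", {
  arch <- small_arch(ld_rho = 0)
  v <- variant_panel(arch, 3)[1:4, ]
  set.seed(3)
  G <- simulate_genotypes(800, v, arch, 3)
  y <- rbinom(800, 1, stats::plogis(-1 + 0.3 * G[, 2]))
  gw <- run_gwas(G, y, trait_label = "x", family = "binomial")
  f <- summary(stats::glm(y ~ G[, 2], family = stats::binomial()))$coefficients
  expect_equal(gw$beta[2], f[2, 1], tolerance = 1e-6)
  expect_equal(gw$se[2], f[2, 2], tolerance = 1e-6)
})

test_that("the scan holds its type-I error under the null", {
  arch <- genetic_architecture(n_child_specific = 1000L, n_adult_specific = 0L,
                               n_shared = 0L, ld_block_size = 1L, ld_rho = 0)
  v <- variant_panel(arch, 4)
  G <- simulate_genotypes(500, v, arch, 4)
  set.seed(5)
  y <- rnorm(500)
  gw <- run_gwas(G, y, trait_label = "null")
  expect_equal(mean(gw$p_value < 0.05), 0.05, tolerance = 0.02 / 0.05)
})

test_that("association betas are unbiased over replicates", {
  arch <- genetic_architecture(n_child_specific = 5L, n_adult_specific = 5L,
                               n_shared = 0L, effect_sd_child = 0.15,
                               effect_sd_adult = 0.15, ld_block_size = 1L, ld_rho = 0)
  v <- variant_panel(arch, 6)
  eff <- draw_variant_effects(v, arch, 6)
  truth <- true_effects(phi = 0.3)
  R <- 200
  betas <- matrix(NA_real_, R, nrow(v))
  for (r in seq_len(R)) {
    G <- simulate_genotypes(1000, v, arch, 1000 + r)
    ph <- simulate_phenotypes(G, v, arch, truth, 2000 + r, effects = eff)
    betas[r, ] <- run_gwas(G, ph$C, trait_label = "C")$beta
  }
  # with independent variants the marginal effect equals gamma_child
  zbias <- abs(colMeans(betas) - eff$gamma_child) / (apply(betas, 2, sd) / sqrt(R))
  expect_gte(mean(zbias <= 2), 0.9)
  expect_true(all(zbias <= 4))
})

test_that("monomorphic variants produce NA rows with a warning", {
  G <- cbind(a = rep(2, 50), b = rbinom(50, 2, 0.5))
  expect_warning(gw <- run_gwas(G, rnorm(50), trait_label = "x"), "monomorphic")
  expect_true(is.na(gw$beta[1]))
  expect_false(is.na(gw$beta[2]))
})

test_that("greedy clumping applies the joint distance-and-LD rule", {
  mk <- function(id, pos, p, eaf = 0.3) {
    data.frame(variant_id = id, chromosome = 1L, position = pos, eaf = eaf,
               beta = 0.1, se = 0.01, p_value = p, n = 1000L, trait = "x",
               stringsAsFactors = FALSE)
  }
  ldm <- function(ids, r2) {
    m <- matrix(r2, length(ids), length(ids), dimnames = list(ids, ids))
    diag(m) <- 1
    m
  }
  # singleton
  s1 <- mk("a", 1e6, 1e-9)
  expect_equal(clump(s1, ldm("a", 0))$stats$variant_id, "a")
  # correlated neighbours 100 kb apart: only the smaller p survives
  s2 <- rbind(mk("a", 1e6, 1e-9), mk("b", 1.1e6, 1e-8))
  expect_equal(clump(s2, ldm(c("a", "b"), 0.5))$stats$variant_id, "a")
  # r2 below threshold: both are independent signals
  expect_setequal(clump(s2, ldm(c("a", "b"), 5e-4))$stats$variant_id, c("a", "b"))
  # correlated but distant (> window): both survive
  s3 <- rbind(mk("a", 1e6, 1e-9), mk("b", 1.4e6, 1e-8))
  expect_setequal(clump(s3, ldm(c("a", "b"), 0.5))$stats$variant_id, c("a", "b"))
  # p and MAF filters
  s4 <- rbind(mk("a", 1e6, 1e-6), mk("b", 2e6, 1e-9, eaf = 0.005))
  expect_warning(empty <- clump(s4, ldm(c("a", "b"), 0)), "empty")
  expect_equal(nrow(empty$stats), 0)
})

test_that("clumped sets satisfy the pairwise independence invariant", {
  arch <- small_arch()
  v <- variant_panel(arch, 8)
  eff <- draw_variant_effects(v, arch, 8)
  G <- simulate_genotypes(4000, v, arch, 8)
  ph <- simulate_phenotypes(G, v, arch, true_effects(), 9, effects = eff)
  gw <- run_gwas(G, rank_inverse_normalise(ph$C), variants = v, trait_label = "C")
  ld <- ld_r2(G, v)
  ins <- clump(gw, ld, p_thresh = 1e-4)
  st <- ins$stats
  expect_gt(nrow(st), 1)
  for (i in seq_len(nrow(st) - 1)) {
    for (j in (i + 1):nrow(st)) {
      same <- st$chromosome[i] == st$chromosome[j]
      near <- abs(st$position[i] - st$position[j]) <= 250 * 1000
      r2 <- ld[st$variant_id[i], st$variant_id[j]]
      expect_true(!(same && near) || r2 <= 0.001)
    }
  }
  expect_true(all(st$p_value <= 1e-4))
  expect_true(all(st$eaf >= 0.01 & st$eaf <= 0.99))
  # deterministic under re-run
  expect_identical(clump(gw, ld, p_thresh = 1e-4)$stats, st)
})

test_that("variance explained follows the 2 beta^2 eaf (1 - eaf) formula", {
  expect_equal(variance_explained(0.1, 0.5), 0.005)
  expect_equal(variance_explained(0, 0.3), 0)
  expect_error(variance_explained(0.1, 1), "eaf")
})

test_that("mean F summarises instrument strength", {
  st <- data.frame(beta = c(0.1), se = c(0.02))
  expect_equal(mean_f_statistic(st), 25)
  st2 <- data.frame(beta = c(0.3, -0.3), se = c(0.1, 0.1))
  expect_equal(mean_f_statistic(st2), 9)
  expect_error(mean_f_statistic(st2[0, ]), "empty")
})

test_that("mean F tracks n times variance explained", {
  arch <- genetic_architecture(n_child_specific = 30L, n_adult_specific = 0L,
                               n_shared = 0L, effect_sd_child = 0.08,
                               ld_block_size = 1L, ld_rho = 0)
  v <- variant_panel(arch, 10)
  v$eaf <- rep(0.5, nrow(v))      # per-variant r2 = 0.08^2 * 0.5 = 0.0032
  eff <- draw_variant_effects(v, arch, 10)
  n <- 20000
  G <- simulate_genotypes(n, v, arch, 10)
  ph <- simulate_phenotypes(G, v, arch, true_effects(), 11, effects = eff)
  gw <- run_gwas(G, ph$C, trait_label = "C")
  expected <- n * mean(variance_explained(eff$gamma_child, v$eaf))
  expect_equal(mean_f_statistic(gw), expected, tolerance = 0.2)
})

test_that("risk scores validate against the phenotype they index", {
  set.seed(12)
  n <- 2000
  G <- cbind(rs1 = rbinom(n, 2, 0.4), rs2 = rbinom(n, 2, 0.6))
  st <- data.frame(variant_id = c("rs1", "rs2"), beta = c(0.5, -0.3),
                   se = 0.01, eaf = c(0.4, 0.6), p_value = 1e-10, n = n,
                   trait = "x", chromosome = 1L, position = c(1, 2) * 1e6)
  ins <- lifecourseMR:::new_instrument_set(st, list())
  # score identical to the phenotype: perfect discrimination
  ph <- drop(G %*% st$beta)
  rep_perf <- suppressWarnings(grs_validate(ins, G, ph))  # perfect separation
  expect_equal(rep_perf$auc, 1)
  expect_equal(rep_perf$variance_explained, 1, tolerance = 1e-10)
  # independent phenotype: null discrimination
  rep_null <- grs_validate(ins, G, rnorm(n))
  expect_equal(rep_null$auc, 0.5, tolerance = 0.04 / 0.5)
  expect_equal(unname(rep_null$odds_ratio), 1, tolerance = 0.15)
  expect_error(grs_validate(ins, G[, 1, drop = FALSE], ph), "fewer than 2")
})

test_that("rank AUC equals exhaustive pair counting", {
  set.seed(13)
  score <- c(rnorm(120), rnorm(80, 0.8))
  case <- rep(c(FALSE, TRUE), c(120, 80))
  wins <- 0
  for (i in which(case)) {
    wins <- wins + sum(score[i] > score[!case]) + 0.5 * sum(score[i] == score[!case])
  }
  expect_equal(auc_rank(score, case), wins / (120 * 80), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(auc_rank(score, case),
                 as.numeric(pROC::auc(pROC::roc(case, score, quiet = TRUE))),
                 tolerance = 1e-10)
  }
})
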