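test_that("variant panel respects its structural invariants", {
  arch <- genetic_architecture()
  v <- variant_panel(arch, 1)
  expect_equal(nrow(v), 300)
  expect_false(anyDuplicated(v$variant_id) > 0)
  expect_true(all(v$eaf > 0 & v$eaf < 1))
  expect_true(all(v$effect_allele != v$other_allele))
  expect_true(all(v$position >= 1))
  # blocks never span chromosomes or mix components
  for (b in unique(v$block)) {
    expect_length(unique(v$chromosome[v$block == b]), 1)
    expect_length(unique(v$component[v$block == b]), 1)
  }
  expect_identical(variant_panel(arch, 1), v)
  expect_false(identical(variant_panel(arch, 2)$eaf, v$eaf))
})

test_that("effect draws make the heritability bookkeeping exact", {
  arch <- genetic_architecture()
  v <- variant_panel(arch, 7)
  eff <- draw_variant_effects(v, arch, 7)
  het <- 2 * v$eaf * (1 - v$eaf)
  for (comp in c("child", "shared")) {
    i <- v$component == comp
    expect_equal(sum(eff$gamma_child[i]^2 * het[i]),
                 arch$effect_sd_child^2 * sum(het[i]),
                 tolerance = 1e-12)
  }
  i <- v$component == "adult"
  expect_equal(sum(eff$gamma_adult_direct[i]^2 * het[i]),
               arch$effect_sd_adult^2 * sum(het[i]), tolerance = 1e-12)
  i <- v$component == "shared"
  expect_equal(sum(eff$gamma_adult_direct[i]^2 * het[i]),
               (arch$effect_sd_shared * arch$shared_adult_scale)^2 * sum(het[i]),
               tolerance = 1e-12)
  # shared effects proportional across the two phenotypes
  expect_equal(stats::cor(eff$gamma_child[i], eff$gamma_adult_direct[i]), 1)
})

test_that("independent variants have the right frequencies and no LD", {
  arch <- small_arch(ld_rho = 0)
  v <- variant_panel(arch, 3)
  v$eaf <- rep(0.5, nrow(v))
  G <- simulate_genotypes(10000, v, arch, 11)
  expect_true(all(G %in% 0:2))
  expect_true(all(abs(colMeans(G) - 1) < 0.03))
  r <- suppressWarnings(stats::cor(G))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("allele frequencies converge to eaf within 3/sqrt(n)", {
  arch <- small_arch()
  v <- variant_panel(arch, 5)
  n <- 10000
  G <- simulate_genotypes(n, v, arch, 5)
  expect_true(all(abs(colMeans(G) / 2 - v$eaf) < 3 / sqrt(n)))
})

test_that("high latent correlation yields highly correlated dosages", {
  arch <- genetic_architecture(n_child_specific = 2L, n_adult_specific = 0L,
                               n_shared = 0L, ld_block_size = 2L, ld_rho = 0.99)
  v <- variant_panel(arch, 1)
  v$eaf <- c(0.5, 0.5)
  G <- simulate_genotypes(10000, v, arch, 9)
  expect_gt(stats::cor(G[, 1], G[, 2]), 0.9)
})

test_that("genotype simulation is deterministic and validates input", {
  arch <- small_arch()
  v <- variant_panel(arch, 2)
  expect_identical(simulate_genotypes(500, v, arch, 42),
                   simulate_genotypes(500, v, arch, 42))
  expect_error(simulate_genotypes(0, v, arch, 1), "n_individuals")
  v_bad <- v
  v_bad$chromosome[v_bad$block == 1][1] <- 22L
  expect_error(simulate_genotypes(10, v_bad, arch, 1), "spans")
})

test_that("null structural model gives mutually uncorrelated phenotypes", {
  arch <- genetic_architecture(n_child_specific = 10L, n_adult_specific = 10L,
                               n_shared = 0L, effect_sd_child = 0,
                               effect_sd_adult = 0, effect_sd_shared = 0,
                               ld_rho = 0)
  v <- variant_panel(arch, 1)
  truth <- true_effects(phi = 0, theta_child = 0, theta_adult = 0,
                        confounder_loadings = c(child = 0, adult = 0, outcome = 0))
  G <- simulate_genotypes(10000, v, arch, 2)
  ph <- simulate_phenotypes(G, v, arch, truth, 3)
  expect_lt(abs(stats::cor(ph$C, ph$A)), 0.03)
  expect_lt(abs(stats::cor(ph$C, ph$Y)), 0.03)
  expect_lt(abs(stats::cor(ph$A, ph$Y)), 0.03)
})

test_that("the childhood-adulthood causal path is recovered by regression", {
  arch <- genetic_architecture(n_child_specific = 10L, n_adult_specific = 10L,
                               n_shared = 0L, effect_sd_child = 0,
                               effect_sd_adult = 0, effect_sd_shared = 0,
                               ld_rho = 0)
  v <- variant_panel(arch, 1)
  truth <- true_effects(phi = 0.5,
                        confounder_loadings = c(child = 0, adult = 0, outcome = 0))
  G <- simulate_genotypes(10000, v, arch, 4)
  ph <- simulate_phenotypes(G, v, arch, truth, 5)
  slope <- stats::coef(stats::lm(ph$A ~ ph$C))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.03 / 0.5)
  expect_equal(stats::var(ph$C), 1, tolerance = 0.05)
  expect_equal(stats::var(ph$A), 1, tolerance = 0.05)
})

test_that("path tracing: genetic score covariance follows phi * theta_adult", {
  # theta_child = 0, phi = 0.5, theta_adult = 0.2, no confounding:
  # cov(Y, childhood score) = 0.5 * 0.2 * cov(score, C)
  arch <- small_arch(ld_rho = 0)
  v <- variant_panel(arch, 6)
  eff <- draw_variant_effects(v, arch, 6)
  truth <- true_effects(phi = 0.5, theta_child = 0, theta_adult = 0.2,
                        confounder_loadings = c(child = 0, adult = 0, outcome = 0))
  G <- simulate_genotypes(20000, v, arch, 7)
  ph <- simulate_phenotypes(G, v, arch, truth, 8, effects = eff)
  score <- drop(G %*% eff$gamma_child)
  ratio <- stats::cov(ph$Y, score) / stats::cov(score, ph$C)
  expect_equal(ratio, 0.10, tolerance = 0.25)
})

test_that("binary outcomes hit the configured prevalence", {
  arch <- small_arch(ld_rho = 0)
  v <- variant_panel(arch, 2)
  truth <- true_effects(phi = 0.3, theta_child = -0.05, theta_adult = 0.6,
                        outcome_type = "binary", binary_prevalence = 0.1)
  G <- simulate_genotypes(20000, v, arch, 3)
  ph <- simulate_phenotypes(G, v, arch, truth, 4)
  expect_true(all(ph$Y %in% 0:1))
  expect_equal(mean(ph$Y), 0.1, tolerance = 0.1)
})

test_that("over-strong architectures are rejected", {
  arch <- small_arch(effect_sd = 2)
  v <- variant_panel(arch, 1)
  truth <- true_effects()
  G <- simulate_genotypes(50, v, arch, 1)
  expect_error(simulate_phenotypes(G, v, arch, truth, 1), "residual variance")
  expect_error(true_effects(outcome_type = "binary"), "binary_prevalence")
  expect_error(true_effects(binary_prevalence = 0.1), "binary")
})

test_that("recall categories follow the cut proportions and stay monotone", {
  set.seed(1)
  x <- rnorm(9000)
  cat0 <- derive_recall_category(x, c(1 / 3, 2 / 3), 0)
  expect_equal(as.numeric(table(cat0)) / length(x), rep(1 / 3, 3), tolerance = 0.01)
  m <- tapply(x, cat0, mean)
  expect_true(m["thinner"] < m["same"] && m["same"] < m["plumper"])
  # heavy misclassification shrinks the between-category separation
  cat49 <- derive_recall_category(x, c(1 / 3, 2 / 3), 0.49, seed = 2)
  gap0 <- diff(range(tapply(x, cat0, mean)))
  gap49 <- diff(range(tapply(x, cat49, mean)))
  expect_lt(gap49, gap0)
  expect_error(derive_recall_category(x, c(0.5, 0.4), 0), "increasing")
  expect_error(derive_recall_category(x, c(1 / 3, 2 / 3), 0.6), "misclass")
})

test_that("two-sample bundles are deterministic, disjoint and truthful", {
  cfg <- list(n_exposure = 300L, n_outcome = 200L,
              architecture = small_arch(), truth = true_effects(theta_adult = 0.3))
  b1 <- build_two_sample_study(cfg, seed = 31)
  b2 <- build_two_sample_study(cfg, seed = 31)
  expect_identical(b1, b2)
  expect_length(intersect(b1$exposure$ids, b1$outcome$ids), 0)
  expect_equal(nrow(b1$exposure$genotypes) + nrow(b1$outcome$genotypes), 500)
  expect_identical(b1$truth, cfg$truth)
  expect_s3_class(b1$exposure$phenotypes$recall, "factor")
})
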