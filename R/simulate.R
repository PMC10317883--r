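#' Simulate genotype dosages with block LD
#'
#' Per LD block, each of the two haplotypes is a latent multivariate normal
#' with exchangeable correlation `ld_rho`, thresholded at the effect-allele
#' frequency quantile; the dosage is the sum of the two haplotype indicators.
#' Blocks are taken as contiguous runs of the `block` column when present,
#' otherwise as consecutive chunks of `ld_block_size` variants. Across blocks
#' the latent draws are independent.
#'
#' @param n_individuals Number of individuals (`>= 1`).
#' @param variants Variant table (see [variant_panel()]).
#' @param architecture A [genetic_architecture()]; supplies `ld_rho` and, when
#'   the variant table carries no `block` column, `ld_block_size`.
#' @param seed Integer seed.
#' @return Dosage matrix (numeric storage, values in `{0, 1, 2}`),
#'   `n_individuals` x `nrow(variants)`, columns named by `variant_id`.
#' @export
simulate_genotypes <- function(n_individuals, variants, architecture, seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  validate_variants(variants)
  rho <- architecture$ld_rho
  if (rho < 0 || rho >= 1) stop("ld_rho must lie in [0, 1)")
  n_var <- nrow(variants)
  block <- if ("block" %in% names(variants)) {
    variants$block
  } else {
    rep(seq_len(ceiling(n_var / architecture$ld_block_size)),
        each = architecture$ld_block_size)[seq_len(n_var)]
  }
  for (b in unique(block)) {
    if (length(unique(variants$chromosome[block == b])) > 1L) {
      stop("LD block ", b, " spans more than one chromosome")
    }
  }

  old <- .Random.seed_exists()
  set.seed(seed)
  G <- sample_block_dosages(as.integer(n_individuals), stats::qnorm(variants$eaf),
                            as.integer(block), rho)
  .restore_seed(old)
  colnames(G) <- variants$variant_id
  G
}

#' Simulate lifecourse phenotypes on a genotype matrix
#'
#' Implements the structural model
#' \deqn{C = G \gamma_C + \lambda_C U + \epsilon_C}
#' \deqn{A = \phi C + G \gamma_A + \lambda_A U + \epsilon_A}
#' \deqn{Y = \theta_C C + \theta_A A + \lambda_Y U + \epsilon_Y}
#' with `U ~ N(0,1)` and residual variances solved analytically so `C` and `A`
#' have total variance 1 (the cross-covariance terms between the `phi` path
#' and the direct adulthood genetics are accounted for). A binary outcome is
#' Bernoulli(logistic(alpha + liability)) with the intercept `alpha` solved on
#' the simulated liabilities to hit `binary_prevalence` within 0.002.
#'
#' Covariates `sex`, `age` and a collapsed `centre` factor are simulated with
#' zero true effect by default; `covariate_effects` adds effects of sex and
#' standardised age on the two exposures to exercise residualisation.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param variants Matching variant table.
#' @param architecture The [genetic_architecture()].
#' @param truth A [true_effects()].
#' @param seed Integer seed.
#' @param effects Optional per-variant effects from [draw_variant_effects()];
#'   drawn from a sub-seed of `seed` when omitted. Pass the same effects to
#'   both cohorts of a study.
#' @param covariate_effects Optional list with numeric `sex` and `age`, each a
#'   length-2 vector `(child, adult)`.
#' @return Data frame with columns `C`, `A`, `Y`, `U`, `sex`, `age`, `centre`;
#'   the effects table and residual variances are attached as attributes.
#' @export
simulate_phenotypes <- function(genotypes, variants, architecture, truth, seed = 1L,
                                effects = NULL,
                                covariate_effects = NULL) {
  if (ncol(genotypes) != nrow(variants)) stop("genotype/variant dimensions disagree")
  if (is.null(effects)) {
    effects <- draw_variant_effects(variants, architecture, seed)
  }
  stopifnot(identical(effects$variant_id, variants$variant_id))
  het <- 2 * variants$eaf * (1 - variants$eaf)
  v_child <- sum(effects$gamma_child^2 * het)
  v_adult <- sum(effects$gamma_adult_direct^2 * het)
  v_cross <- sum(effects$gamma_child * effects$gamma_adult_direct * het)
  lam <- truth$confounder_loadings
  phi <- truth$phi

  res_child <- 1 - v_child - lam[["child"]]^2
  if (res_child <= 0) stop("architecture too strong: childhood residual variance <= 0")
  res_adult <- 1 - (phi^2 + v_adult + lam[["adult"]]^2 +
                      2 * phi * (v_cross + lam[["child"]] * lam[["adult"]]))
  if (res_adult <= 0) stop("architecture too strong: adulthood residual variance <= 0")

  n <- nrow(genotypes)
  old <- .Random.seed_exists()
  set.seed(seed)
  U <- stats::rnorm(n)
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- stats::rnorm(n, 55, 8)
  centre <- factor(sample(paste0("centre", 1:8), n, replace = TRUE))

  Gc <- drop(genotypes %*% effects$gamma_child)
  Ga <- drop(genotypes %*% effects$gamma_adult_direct)
  C <- Gc + lam[["child"]] * U + stats::rnorm(n, sd = sqrt(res_child))
  A <- phi * C + Ga + lam[["adult"]] * U + stats::rnorm(n, sd = sqrt(res_adult))
  if (!is.null(covariate_effects)) {
    age_z <- (age - 55) / 8
    C <- C + covariate_effects$sex[1] * sex + covariate_effects$age[1] * age_z
    A <- A + covariate_effects$sex[2] * sex + covariate_effects$age[2] * age_z
  }

  cov_CA <- phi + v_cross + lam[["child"]] * lam[["adult"]]
  eta <- truth$theta_child * C + truth$theta_adult * A + lam[["outcome"]] * U
  if (truth$outcome_type == "continuous") {
    var_struct <- truth$theta_child^2 + truth$theta_adult^2 +
      2 * truth$theta_child * truth$theta_adult * cov_CA + lam[["outcome"]]^2
    res_y <- max(1 - var_struct, 0.05)
    Y <- eta + stats::rnorm(n, sd = sqrt(res_y))
  } else {
    res_y <- NA_real_
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + eta)) - truth$binary_prevalence,
      interval = c(-40, 40), tol = 1e-10
    )$root
    Y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
  }
  .restore_seed(old)

  out <- data.frame(C = C, A = A, Y = Y, U = U, sex = sex, age = age, centre = centre)
  attr(out, "effects") <- effects
  attr(out, "residual_variances") <- c(child = res_child, adult = res_adult, outcome = res_y)
  out
}

#' Collapse a continuous childhood value to a 3-level recall variable
#'
#' Emulates the retrospective body-size recall question: each individual is
#' labelled `thinner`, `same` or `plumper` according to the empirical quantile
#' of their true childhood value against the cut proportions; with probability
#' `misclass_prob` a label is moved to an adjacent category (the middle
#' category moves up or down with equal probability).
#'
#' @param child_values Numeric vector of true childhood values.
#' @param cut_proportions Two strictly increasing fractions in (0, 1).
#' @param misclass_prob Adjacent-category misclassification probability,
#'   in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return Factor with levels `thinner < same < plumper`.
#' @export
derive_recall_category <- function(child_values, cut_proportions = c(1 / 3, 2 / 3),
                                   misclass_prob = 0, seed = 1L) {
  p <- cut_proportions
  if (length(p) != 2 || !(0 < p[1] && p[1] < p[2] && p[2] < 1)) {
    stop("cut_proportions must be strictly increasing within (0, 1)")
  }
  if (misclass_prob < 0 || misclass_prob >= 0.5) stop("misclass_prob must lie in [0, 0.5)")
  n <- length(child_values)
  u <- (rank(child_values, ties.method = "first") - 0.5) / n
  lev <- c("thinner", "same", "plumper")
  cat_i <- 1L + (u >= p[1]) + (u >= p[2])
  if (misclass_prob > 0) {
    old <- .Random.seed_exists()
    set.seed(seed)
    move <- stats::runif(n) < misclass_prob
    dir <- ifelse(cat_i == 1L, 1L, ifelse(cat_i == 3L, -1L, sample(c(-1L, 1L), n, TRUE)))
    .restore_seed(old)
    cat_i[move] <- cat_i[move] + dir[move]
  }
  factor(lev[cat_i], levels = lev)
}

#' Build a complete simulated two-sample MR study
#'
#' Generates an exposure cohort (genotypes, lifecourse phenotypes, recall
#' category, covariates) and a disjoint outcome cohort sharing the variant
#' panel and true effects but no individuals, plus an optional validation
#' cohort for score validation. All stages draw from labelled sub-streams of
#' one master seed, so identical seeds give identical bundles.
#'
#' @param config List with elements `n_exposure`, `n_outcome`, optional
#'   `n_validation` (default 0), `architecture` ([genetic_architecture()]),
#'   `truth` ([true_effects()]), optional `recall` list (`cut_proportions`,
#'   `misclass_prob`) and optional `covariate_effects`.
#' @param seed Master integer seed.
#' @return A `study_bundle`: list with `variants`, `effects`, `truth`,
#'   `architecture`, cohorts `exposure`, `outcome`, optionally `validation`
#'   (each `list(ids, genotypes, phenotypes)`), the recall settings and the
#'   seed.
#' @export
build_two_sample_study <- function(config, seed = 1L) {
  stopifnot(config$n_exposure >= 1, config$n_outcome >= 1)
  arch <- config$architecture
  truth <- config$truth
  recall <- config$recall
  if (is.null(recall)) recall <- list(cut_proportions = c(1 / 3, 2 / 3), misclass_prob = 0.1)
  n_val <- if (is.null(config$n_validation)) 0L else config$n_validation

  variants <- variant_panel(arch, seed)
  effects <- draw_variant_effects(variants, arch, seed)

  cohort <- function(n, geno_stage, pheno_stage, prefix) {
    G <- simulate_genotypes(n, variants, arch, sub_seed(seed, geno_stage))
    ph <- simulate_phenotypes(G, variants, arch, truth, sub_seed(seed, pheno_stage),
                              effects = effects,
                              covariate_effects = config$covariate_effects)
    list(ids = sprintf("%s%06d", prefix, seq_len(n)), genotypes = G, phenotypes = ph)
  }
  exposure <- cohort(config$n_exposure, "genotypes_exposure", "phenotypes_exposure", "EXP")
  exposure$phenotypes$recall <- derive_recall_category(
    exposure$phenotypes$C, recall$cut_proportions, recall$misclass_prob,
    sub_seed(seed, "recall")
  )
  outcome <- cohort(config$n_outcome, "genotypes_outcome", "phenotypes_outcome", "OUT")
  validation <- if (n_val > 0) {
    cohort(n_val, "genotypes_validation", "phenotypes_validation", "VAL")
  }

  structure(list(
    variants = variants, effects = effects, truth = truth, architecture = arch,
    recall = recall, exposure = exposure, outcome = outcome, validation = validation,
    seed = seed
  ), class = "study_bundle")
}
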