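#' Genetic architecture of the simulated exposures
#'
#' Describes the variant panel feeding the two lifecourse exposures: how many
#' variants act only on the childhood phenotype, only on the adulthood
#' phenotype, or on both (shared), the per-allele effect-size scale of each
#' component, and the block linkage-disequilibrium structure the panel is
#' embedded in.
#'
#' Effect-size scales are per-allele standard deviations on the unit-variance
#' phenotype scale, so a component's expected contribution to a phenotype's
#' variance is `effect_sd^2 * sum(2 * eaf * (1 - eaf))` over its variants.
#' Shared variants act on both phenotypes with proportional effects; their
#' adulthood effect is the childhood effect scaled by `shared_adult_scale`.
#'
#' The defaults give 300 variants (100 childhood-specific, 150
#' adulthood-specific, 50 shared) in blocks of 5 with within-block latent
#' correlation 0.3, and per-variant effects sized so a cohort of 20,000 yields
#' single-variant F-statistics around 60 — the per-variant strength implied by
#' large-biobank BMI instruments.
#'
#' @param n_child_specific,n_adult_specific,n_shared Variant counts per
#'   component (all `>= 0`, at least one positive).
#' @param effect_sd_child,effect_sd_adult,effect_sd_shared Per-allele effect
#'   standard deviations (phenotype SD units).
#' @param shared_adult_scale Multiplier applied to a shared variant's childhood
#'   effect to obtain its direct adulthood effect.
#' @param ld_block_size Number of adjacent variants per LD block.
#' @param ld_rho Within-block latent haplotype correlation, in `[0, 1)`.
#' @return An object of class `genetic_architecture` (a validated list).
#' @export
genetic_architecture <- function(n_child_specific = 100L,
                                 n_adult_specific = 150L,
                                 n_shared = 50L,
                                 effect_sd_child = 0.0874,
                                 effect_sd_adult = 0.0874,
                                 effect_sd_shared = 0.0874,
                                 shared_adult_scale = 1 / sqrt(2),
                                 ld_block_size = 5L,
                                 ld_rho = 0.3) {
  counts <- c(n_child_specific, n_adult_specific, n_shared)
  if (any(counts < 0) || !any(counts > 0)) {
    stop("variant counts must be >= 0 with at least one positive")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (any(c(effect_sd_child, effect_sd_adult, effect_sd_shared) < 0)) {
    stop("effect standard deviations must be non-negative")
  }
  structure(list(
    n_child_specific = as.integer(n_child_specific),
    n_adult_specific = as.integer(n_adult_specific),
    n_shared = as.integer(n_shared),
    effect_sd_child = effect_sd_child,
    effect_sd_adult = effect_sd_adult,
    effect_sd_shared = effect_sd_shared,
    shared_adult_scale = shared_adult_scale,
    ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho
  ), class = "genetic_architecture")
}

#' True causal parameters of a simulated study
#'
#' The three causal arrows of the lifecourse model — the childhood-to-adulthood
#' path `phi` and the two direct exposure-outcome effects — plus the loadings
#' of the shared confounder `U` on each phenotype, and the outcome type.
#'
#' @param phi Causal effect of the childhood phenotype on the adulthood
#'   phenotype (SD per SD).
#' @param theta_child,theta_adult Direct effects of the childhood and adulthood
#'   phenotypes on the outcome (per exposure SD; log-odds per SD when
#'   `outcome_type = "binary"`).
#' @param confounder_loadings Named numeric vector with elements `child`,
#'   `adult`, `outcome`: effects of the standard-normal confounder `U`.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param binary_prevalence Outcome prevalence in `(0, 1)`; required iff the
#'   outcome is binary.
#' @return An object of class `true_effects`.
#' @export
true_effects <- function(phi = 0.3,
                         theta_child = 0,
                         theta_adult = 0,
                         confounder_loadings = c(child = 0.15, adult = 0.15, outcome = 0.15),
                         outcome_type = c("continuous", "binary"),
                         binary_prevalence = NULL) {
  outcome_type <- match.arg(outcome_type)
  need <- c("child", "adult", "outcome")
  if (!all(need %in% names(confounder_loadings))) {
    stop("confounder_loadings must be named with 'child', 'adult', 'outcome'")
  }
  if (outcome_type == "binary") {
    if (is.null(binary_prevalence) || binary_prevalence <= 0 || binary_prevalence >= 1) {
      stop("binary_prevalence in (0, 1) required for a binary outcome")
    }
  } else if (!is.null(binary_prevalence)) {
    stop("binary_prevalence only applies to binary outcomes")
  }
  structure(list(
    phi = phi,
    theta_child = theta_child,
    theta_adult = theta_adult,
    confounder_loadings = confounder_loadings[need],
    outcome_type = outcome_type,
    binary_prevalence = binary_prevalence
  ), class = "true_effects")
}

#' Build the variant panel implied by an architecture
#'
#' Lays the panel out in contiguous LD blocks, each block homogeneous in
#' component (childhood-specific variants first, then adulthood-specific, then
#' shared), with blocks spread over chromosomes 1-22, 1 Mb between block starts
#' and 5 kb between variants within a block. Effect-allele frequencies are
#' drawn uniformly on (0.1, 0.9); allele pairs are drawn from the four bases so
#' palindromic (A/T, C/G) variants occur at a realistic rate.
#'
#' @param architecture A [genetic_architecture()].
#' @param seed Integer seed.
#' @return A data frame of class `variant_panel` with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`, `eaf`,
#'   `component`, `block`.
#' @export
variant_panel <- function(architecture = genetic_architecture(), seed = 1L) {
  arch <- architecture
  n <- arch$n_child_specific + arch$n_adult_specific + arch$n_shared
  component <- rep(c("child", "adult", "shared"),
                   c(arch$n_child_specific, arch$n_adult_specific, arch$n_shared))
  # blocks are cut within each component so LD never mixes age-specific effects
  block <- integer(n)
  b0 <- 0L
  for (comp in unique(component)) {
    idx <- which(component == comp)
    local <- rep(seq_len(ceiling(length(idx) / arch$ld_block_size)),
                 each = arch$ld_block_size)[seq_along(idx)]
    block[idx] <- b0 + local
    b0 <- b0 + max(local)
  }
  n_blocks <- max(block)
  chrom_of_block <- ((seq_len(n_blocks) - 1L) %% 22L) + 1L
  block_rank <- stats::ave(seq_len(n_blocks), chrom_of_block, FUN = seq_along)

  withr_seed <- sub_seed(seed, "panel")
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  eaf <- stats::runif(n, 0.1, 0.9)
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
  .restore_seed(old)

  within <- stats::ave(seq_len(n), block, FUN = seq_along)
  position <- (block_rank[block] - 1L) * 1000000L + (within - 1L) * 5000L + 1L
  out <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(n)),
    chromosome = chrom_of_block[block],
    position = position,
    effect_allele = ea,
    other_allele = oa,
    eaf = eaf,
    component = component,
    block = block,
    stringsAsFactors = FALSE
  )
  validate_variants(out)
  class(out) <- c("variant_panel", "data.frame")
  out
}

validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  need <- c("variant_id", "chromosome", "position", "effect_allele", "other_allele", "eaf")
  missing <- setdiff(need, names(variants))
  if (length(missing)) stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(variants$variant_id)) stop("duplicated variant ids")
  if (any(variants$eaf <= 0 | variants$eaf >= 1)) stop("eaf must lie strictly in (0, 1)")
  if (any(variants$position < 1)) stop("positions are 1-based")
  if (any(variants$effect_allele == variants$other_allele)) stop("alleles must differ")
  invisible(variants)
}

#' Draw per-variant causal effects for an architecture
#'
#' Effects are drawn from zero-mean normals with the architecture's per-allele
#' scales and then rescaled so each component's realised genetic variance
#' `sum(2 * gamma^2 * eaf * (1 - eaf))` equals its configured value exactly —
#' this makes the heritability bookkeeping of the simulation exact by
#' construction. Shared variants get proportional effects on both phenotypes.
#'
#' @param variants A [variant_panel()] (needs `component` and `eaf`).
#' @param architecture The matching [genetic_architecture()].
#' @param seed Integer seed.
#' @return Data frame with `variant_id`, `gamma_child` (total per-allele effect
#'   on the childhood phenotype) and `gamma_adult_direct` (direct per-allele
#'   effect on the adulthood phenotype, excluding the `phi` path), plus the
#'   component label.
#' @export
draw_variant_effects <- function(variants, architecture, seed = 1L) {
  arch <- architecture
  het <- 2 * variants$eaf * (1 - variants$eaf)
  old <- .Random.seed_exists()
  set.seed(sub_seed(seed, "effects"))
  raw <- stats::rnorm(nrow(variants))
  .restore_seed(old)

  gamma_child <- numeric(nrow(variants))
  gamma_adult <- numeric(nrow(variants))
  rescale <- function(idx, sd) {
    if (!length(idx) || sd == 0) return(numeric(length(idx)))
    g <- raw[idx] * sd
    target <- sd^2 * sum(het[idx])
    g * sqrt(target / sum(g^2 * het[idx]))
  }
  i_child <- which(variants$component == "child")
  i_adult <- which(variants$component == "adult")
  i_shared <- which(variants$component == "shared")
  gamma_child[i_child] <- rescale(i_child, arch$effect_sd_child)
  gamma_adult[i_adult] <- rescale(i_adult, arch$effect_sd_adult)
  g_sh <- rescale(i_shared, arch$effect_sd_shared)
  gamma_child[i_shared] <- g_sh
  gamma_adult[i_shared] <- g_sh * arch$shared_adult_scale

  data.frame(
    variant_id = variants$variant_id,
    component = variants$component,
    gamma_child = gamma_child,
    gamma_adult_direct = gamma_adult,
    stringsAsFactors = FALSE
  )
}

# Labelled sub-streams: one master seed, fixed offsets per stage, so each
# stage is independently reproducible. Kept well below 2^31.
.stage_offsets <- c(
  panel = 101, effects = 211, genotypes_exposure = 307, phenotypes_exposure = 401,
  recall = 503, assign = 601, genotypes_outcome = 701, phenotypes_outcome = 809,
  genotypes_validation = 907, phenotypes_validation = 1009, orientation = 1103,
  missing = 1201, generic = 1301
)

#' Derive a labelled sub-seed from a master seed
#'
#' @param seed Master integer seed.
#' @param stage Stage label (one of the fixed labels) or a non-negative
#'   integer offset, e.g. a replicate index.
#' @return An integer seed in `[0, 2^31)`.
#' @export
sub_seed <- function(seed, stage) {
  offset <- if (is.character(stage)) {
    if (!stage %in% names(.stage_offsets)) stop("unknown stage label: ", stage)
    .stage_offsets[[stage]]
  } else {
    5e4 + as.numeric(stage)
  }
  as.integer(((abs(as.numeric(seed)) %% 97711) * 20011 + offset * 131) %% 2147483647)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
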