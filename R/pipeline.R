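#' Default pipeline configuration
#'
#' A plain (YAML-serialisable) nested list describing the full study: cohort
#' sizes, genetic architecture, shared causal structure, recall construction,
#' instrument-selection thresholds, MR settings, and the outcome menu. The
#' default menu mirrors a diabetes-trait study: seven oral-glucose-tolerance
#' traits, fasting glucose, fasting insulin (continuous), and one binary
#' disease outcome measured in two studies that are meta-analysed. Direct
#' effects are configured so the childhood exposure is protective (or null)
#' and the adulthood exposure damaging, on each trait's natural orientation.
#'
#' @param ... Named top-level overrides (`cohorts`, `architecture`, `truth`,
#'   `recall`, `construction`, `selection`, `mr`, `outcomes`). Each replaces
#'   the corresponding default block.
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    cohorts = list(n_exposure = 20000L, n_outcome = 20000L, n_validation = 5000L),
    architecture = list(
      n_child_specific = 100L, n_adult_specific = 150L, n_shared = 50L,
      effect_sd_child = 0.0874, effect_sd_adult = 0.0874, effect_sd_shared = 0.0874,
      shared_adult_scale = 1 / sqrt(2), ld_block_size = 5L, ld_rho = 0.3
    ),
    truth = list(phi = 0.3, confounder = list(child = 0.15, adult = 0.15, outcome = 0.15)),
    recall = list(cut_proportions = c(1 / 3, 2 / 3), misclass_prob = 0.1),
    construction = list(use_recall = TRUE,
                        reference = list(family = "normal", location = 17.8, scale = 2.8)),
    selection = list(p_thresh = 5e-8, r2_thresh = 0.001, window_kb = 250,
                     maf_bounds = c(0.01, 0.99)),
    mr = list(run_egger = TRUE, run_steiger = TRUE, egger_flag_p = 0.01,
              proxy_r2_min = 0.8, proxy_window_kb = 250,
              outcome_missing_rate = 0.02, randomise_orientation = TRUE),
    outcomes = list(
      auc_insulin       = list(type = "continuous", theta_child = -0.15, theta_adult = 0.25),
      cir               = list(type = "continuous", theta_child = -0.10, theta_adult = 0.15),
      auc_ratio         = list(type = "continuous", theta_child = -0.12, theta_adult = 0.20),
      ins30_bmi_adj     = list(type = "continuous", theta_child = -0.12, theta_adult = 0.18),
      ins30             = list(type = "continuous", theta_child = -0.08, theta_adult = 0.22),
      incremental_ins30 = list(type = "continuous", theta_child = -0.10, theta_adult = 0.20),
      isi               = list(type = "continuous", theta_child = 0.15, theta_adult = -0.30),
      fasting_glucose   = list(type = "continuous", theta_child = -0.05, theta_adult = 0.09),
      fasting_insulin   = list(type = "continuous", theta_child = 0.00, theta_adult = 0.17),
      t2d               = list(type = "binary", theta_child = -0.06, theta_adult = 0.90,
                               prevalence = 0.10, n_studies = 2L)
    )
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML path; top-level blocks as in [default_config()]. Missing
#'   blocks fall back to the defaults.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

config_objects <- function(config) {
  arch <- do.call(genetic_architecture, config$architecture)
  conf <- unlist(config$truth$confounder)[c("child", "adult", "outcome")]
  list(
    architecture = arch,
    confounder = conf,
    phi = config$truth$phi,
    reference = do.call(reference_distribution, config$construction$reference)
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full lifecourse MR pipeline on synthetic data
#'
#' Simulate the exposure cohort; construct the childhood phenotype from the
#' recall variable by anchored assignment (unless
#' `construction$use_recall = FALSE`, in which case the directly simulated
#' childhood value is analysed); rank inverse-normalise and residualise both
#' exposures; run both exposure GWAS; clump each into instrument sets;
#' validate genetic risk scores in a held-out cohort; then, for every
#' configured outcome and study, simulate a disjoint outcome cohort, compute
#' its outcome GWAS (with randomised allele orientation and optional missing
#' variants, so harmonisation and proxy lookup are exercised), and estimate
#' univariable IVW, MR-Egger, multivariable MR, and their Steiger-filtered
#' versions, meta-analysing multi-study outcomes with a fixed-effect model.
#'
#' @param config Configuration from [default_config()].
#' @param seed Master integer seed; every stage derives a labelled sub-seed,
#'   so reruns are byte-identical.
#' @param out_dir Optional output directory; stage TSVs and a hashed manifest
#'   are written when given.
#' @param quiet Suppress progress messages.
#' @return A `results_bundle`: list with `results` (stacked MR result rows),
#'   `instruments` (child/adult instrument sets), `validation` (score
#'   validation reports), `exposure_gwas`, `truth` parameters, `config`,
#'   `seed`, and `files` when `out_dir` was given.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L, out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  obj <- config_objects(config)
  arch <- obj$architecture
  sel <- config$selection

  # --- simulate exposure cohort -------------------------------------------
  truth0 <- true_effects(phi = obj$phi, theta_child = 0, theta_adult = 0,
                         confounder_loadings = obj$confounder)
  variants <- with_stage("simulate", variant_panel(arch, seed))
  effects <- with_stage("simulate", draw_variant_effects(variants, arch, seed))
  G_exp <- with_stage("simulate",
    simulate_genotypes(config$cohorts$n_exposure, variants, arch,
                       sub_seed(seed, "genotypes_exposure")))
  ph_exp <- with_stage("simulate",
    simulate_phenotypes(G_exp, variants, arch, truth0,
                        sub_seed(seed, "phenotypes_exposure"), effects = effects))
  say("exposure cohort: %d individuals x %d variants", nrow(G_exp), ncol(G_exp))

  # --- construct and prepare phenotypes -----------------------------------
  child_raw <- with_stage("construct", {
    if (isTRUE(config$construction$use_recall)) {
      recall <- derive_recall_category(ph_exp$C, config$recall$cut_proportions,
                                       config$recall$misclass_prob,
                                       sub_seed(seed, "recall"))
      assign_continuous(recall, obj$reference, sub_seed(seed, "assign"))
    } else {
      ph_exp$C
    }
  })
  covars <- ph_exp[, c("sex", "age", "centre")]
  child_an <- with_stage("construct", residualise(rank_inverse_normalise(child_raw), covars))
  adult_an <- with_stage("construct", residualise(rank_inverse_normalise(ph_exp$A), covars))

  # --- exposure GWAS and instrument selection -----------------------------
  gwas_child <- with_stage("gwas",
    run_gwas(G_exp, child_an, variants = variants, trait_label = "childhood"))
  gwas_adult <- with_stage("gwas",
    run_gwas(G_exp, adult_an, variants = variants, trait_label = "adulthood"))
  r_signed <- with_stage("clump", {
    r <- panel_cor(G_exp)
    same_chr <- outer(variants$chromosome, variants$chromosome, "==")
    r[!same_chr] <- 0
    diag(r) <- 1
    r
  })
  ld <- r_signed^2
  instr_child <- with_stage("clump",
    clump(gwas_child, ld, sel$p_thresh, sel$r2_thresh, sel$window_kb, sel$maf_bounds))
  instr_adult <- with_stage("clump",
    clump(gwas_adult, ld, sel$p_thresh, sel$r2_thresh, sel$window_kb, sel$maf_bounds))
  say("instruments: %d childhood (R2=%.3f%%, F=%.0f), %d adulthood (R2=%.3f%%, F=%.0f)",
      nrow(instr_child$stats), 100 * instr_child$variance_explained, instr_child$mean_f,
      nrow(instr_adult$stats), 100 * instr_adult$variance_explained, instr_adult$mean_f)

  # --- score validation in a held-out cohort ------------------------------
  validation <- NULL
  if (config$cohorts$n_validation > 0) {
    validation <- with_stage("validate", {
      G_val <- simulate_genotypes(config$cohorts$n_validation, variants, arch,
                                  sub_seed(seed, "genotypes_validation"))
      ph_val <- simulate_phenotypes(G_val, variants, arch, truth0,
                                    sub_seed(seed, "phenotypes_validation"),
                                    effects = effects)
      safe <- function(ins, ph) tryCatch(grs_validate(ins, G_val, ph),
                                         error = function(e) NULL)
      list(child_on_child = safe(instr_child, ph_val$C),
           child_on_adult = safe(instr_child, ph_val$A),
           adult_on_adult = safe(instr_adult, ph_val$A),
           adult_on_child = safe(instr_adult, ph_val$C))
    })
    if (!is.null(validation$child_on_child)) {
      say("childhood score: R2 %.3f on childhood vs %.3f on adulthood phenotype",
          validation$child_on_child$variance_explained,
          validation$child_on_adult$variance_explained)
    }
  }

  # --- per-outcome two-sample MR ------------------------------------------
  union_ids <- union(instr_child$stats$variant_id, instr_adult$stats$variant_id)
  results <- list()
  for (oi in seq_along(config$outcomes)) {
    oname <- names(config$outcomes)[oi]
    ospec <- config$outcomes[[oi]]
    n_studies <- if (is.null(ospec$n_studies)) 1L else ospec$n_studies
    study_rows <- list()
    for (si in seq_len(n_studies)) {
      olabel <- if (n_studies > 1) sprintf("%s_study%d", oname, si) else oname
      rows <- with_stage(paste0("mr:", olabel),
        analyse_outcome(config, obj, variants, arch, effects, oi, si, seed,
                        gwas_child, gwas_adult, instr_child, instr_adult,
                        union_ids, r_signed, ld, olabel))
      study_rows[[si]] <- rows
      results[[length(results) + 1]] <- rows
      say("outcome %s: %d result rows", olabel, nrow(rows))
    }
    if (n_studies > 1) {
      pooled <- with_stage(paste0("meta:", oname), {
        all_rows <- do.call(rbind, study_rows)
        key <- unique(all_rows[, c("method", "exposure", "steiger_filtered")])
        out <- lapply(seq_len(nrow(key)), function(i) {
          sub <- all_rows[all_rows$method == key$method[i] &
                            all_rows$exposure == key$exposure[i] &
                            all_rows$steiger_filtered == key$steiger_filtered[i], ]
          fixed_effect_meta(sub, outcome = oname)
        })
        do.call(rbind, out)
      })
      results[[length(results) + 1]] <- pooled
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  out <- structure(list(
    results = results,
    instruments = list(child = instr_child, adult = instr_adult),
    validation = validation,
    exposure_gwas = list(child = gwas_child, adult = gwas_adult),
    truth = list(phi = obj$phi, confounder = obj$confounder,
                 outcomes = config$outcomes),
    config = config, seed = seed
  ), class = "results_bundle")

  if (!is.null(out_dir)) {
    out$files <- with_stage("write", write_results_bundle(out, out_dir))
  }
  out
}

# Simulate one outcome study and run every configured estimator on it.
analyse_outcome <- function(config, obj, variants, arch, effects, oi, si, seed,
                            gwas_child, gwas_adult, instr_child, instr_adult,
                            union_ids, r_signed, ld, olabel) {
  ospec <- config$outcomes[[oi]]
  mrc <- config$mr
  truth <- true_effects(
    phi = obj$phi, theta_child = ospec$theta_child, theta_adult = ospec$theta_adult,
    confounder_loadings = obj$confounder,
    outcome_type = ospec$type,
    binary_prevalence = if (ospec$type == "binary") ospec$prevalence
  )
  off <- 2000 + oi * 20 + si
  G_out <- simulate_genotypes(config$cohorts$n_outcome, variants, arch,
                              sub_seed(seed, off))
  ph_out <- simulate_phenotypes(G_out, variants, arch, truth,
                                sub_seed(seed, off + 1), effects = effects)
  gwas_out <- run_gwas(G_out, ph_out$Y, variants = variants, trait_label = olabel,
                       family = if (ospec$type == "binary") "binomial" else "gaussian")
  published <- publish_outcome_stats(gwas_out, mrc, sub_seed(seed, off + 2))

  h_child <- harmonise(gwas_child, published)
  h_adult <- harmonise(gwas_adult, published)
  h_mvmr <- harmonise_mvmr(gwas_child, gwas_adult, published)

  sub <- function(h, ids, exp_stats) {
    subset_with_proxies(h, ids, exp_stats, published, r_signed, ld, variants,
                        mrc$proxy_r2_min, mrc$proxy_window_kb)
  }
  hc <- sub(h_child, instr_child$stats$variant_id, gwas_child)
  ha <- sub(h_adult, instr_adult$stats$variant_id, gwas_adult)
  hm <- h_mvmr[h_mvmr$variant_id %in% union_ids, , drop = FALSE]

  rows <- list(
    mr_ivw(hc, "childhood", olabel),
    mr_ivw(ha, "adulthood", olabel),
    mr_mvmr(hm, c("childhood", "adulthood"), olabel)
  )
  if (isTRUE(mrc$run_egger)) {
    rows <- c(rows, list(mr_egger(hc, "childhood", olabel),
                         mr_egger(ha, "adulthood", olabel)))
  }
  if (isTRUE(mrc$run_steiger)) {
    rows <- c(rows, list(
      mr_ivw(steiger_filter(hc), "childhood", olabel),
      mr_ivw(steiger_filter(ha), "adulthood", olabel),
      mr_mvmr(steiger_filter(hm), c("childhood", "adulthood"), olabel)
    ))
  }
  do.call(rbind, rows)
}

# Emulate an externally published outcome GWAS: randomise which allele each
# row is reported against and drop a fraction of variants, so harmonisation
# and proxy search face realistic input.
publish_outcome_stats <- function(gwas_out, mrc, seed) {
  out <- gwas_out
  old <- .Random.seed_exists()
  set.seed(seed)
  if (isTRUE(mrc$randomise_orientation)) {
    flip <- stats::runif(nrow(out)) < 0.5
    ea <- out$effect_allele
    out$effect_allele[flip] <- out$other_allele[flip]
    out$other_allele[flip] <- ea[flip]
    out$beta[flip] <- -out$beta[flip]
    out$eaf[flip] <- 1 - out$eaf[flip]
  }
  rate <- mrc$outcome_missing_rate
  if (!is.null(rate) && rate > 0) {
    out <- out[stats::runif(nrow(out)) >= rate, , drop = FALSE]
  }
  .restore_seed(old)
  out
}

# Restrict a harmonised set to an instrument list, proxying instruments the
# published outcome GWAS lacks: the index variant keeps its own exposure
# effect while the proxy's outcome effect is borrowed, sign-aligned by the
# dosage correlation between index and proxy.
subset_with_proxies <- function(h, instrument_ids, exposure_stats, published,
                                r_signed, ld, variants, r2_min, window_kb) {
  have <- instrument_ids[instrument_ids %in% h$variant_id]
  out <- h[match(have, h$variant_id), , drop = FALSE]
  missing <- setdiff(instrument_ids, have)
  for (id in missing) {
    pool <- intersect(h$variant_id, colnames(ld))
    proxy <- find_proxy(id, setdiff(pool, id), ld, variants, r2_min, window_kb)
    if (is.na(proxy)) next
    prow <- h[h$variant_id == proxy, ]
    erow <- exposure_stats[exposure_stats$variant_id == id, ]
    srow <- prow
    srow$variant_id <- id
    srow$chromosome <- erow$chromosome
    srow$position <- erow$position
    srow$effect_allele <- erow$effect_allele
    srow$other_allele <- erow$other_allele
    srow$eaf <- erow$eaf
    srow$beta_exposure <- erow$beta
    srow$se_exposure <- erow$se
    srow$beta_outcome <- sign(r_signed[id, proxy]) * prow$beta_outcome
    srow$proxy_used <- TRUE
    out <- rbind(out, srow)
  }
  rownames(out) <- NULL
  class(out) <- class(h)
  out
}

write_results_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    files <<- c(files, p)
    p
  }
  wt(bundle$results, "mr_results.tsv")
  write_sumstats(bundle$exposure_gwas$child, file.path(out_dir, "gwas_childhood.tsv"))
  write_sumstats(bundle$exposure_gwas$adult, file.path(out_dir, "gwas_adulthood.tsv"))
  files <- c(files, file.path(out_dir, c("gwas_childhood.tsv", "gwas_adulthood.tsv")))
  wt(bundle$instruments$child$stats, "instruments_childhood.tsv")
  wt(bundle$instruments$adult$stats, "instruments_adulthood.tsv")
  if (!is.null(bundle$validation)) {
    v <- bundle$validation
    rows <- do.call(rbind, lapply(names(v), function(nm) {
      if (is.null(v[[nm]])) return(NULL)
      data.frame(comparison = nm, odds_ratio = v[[nm]]$odds_ratio,
                 or_ci_low = v[[nm]]$or_ci[1], or_ci_high = v[[nm]]$or_ci[2],
                 or_p = v[[nm]]$or_p, auc = v[[nm]]$auc,
                 variance_explained = v[[nm]]$variance_explained,
                 n = v[[nm]]$n, n_instruments = v[[nm]]$n_instruments)
    }))
    if (!is.null(rows)) wt(rows, "score_validation.tsv")
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(bundle$config, cfg_path)
  files <- c(files, cfg_path)
  write_manifest(files, file.path(out_dir, "manifest.tsv"),
                 meta = c(seed = as.character(bundle$seed),
                          config_md5 = unname(tools::md5sum(cfg_path))))
  c(files, file.path(out_dir, "manifest.tsv"))
}
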