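#!/usr/bin/env Rscript
# Simulate the synthetic two-sample study: an exposure cohort with childhood
# and adulthood phenotypes under the lifecourse causal model, and a disjoint
# outcome cohort, and check the generator's bookkeeping (allele frequencies,
# unit phenotype variances, exact genetic-variance accounting).

source("analysis/_common.R")

arch <- do.call(genetic_architecture, CFG$architecture)
truth <- true_effects(phi = CFG$truth$phi, theta_child = -0.05, theta_adult = 0.15,
                      confounder_loadings = unlist(CFG$truth$confounder))
study <- build_two_sample_study(
  list(n_exposure = CFG$cohorts$n_exposure, n_outcome = CFG$cohorts$n_outcome,
       architecture = arch, truth = truth, recall = CFG$recall),
  seed = SEED
)

v <- study$variants
G <- study$exposure$genotypes
ph <- study$exposure$phenotypes

message(sprintf("exposure cohort: %d individuals; outcome cohort: %d; %d variants in %d LD blocks",
                nrow(G), nrow(study$outcome$genotypes), nrow(v), max(v$block)))
message(sprintf("max |empirical - configured| allele frequency: %.4f (tolerance 3/sqrt(n) = %.4f)",
                max(abs(colMeans(G) / 2 - v$eaf)), 3 / sqrt(nrow(G))))
message(sprintf("phenotype variances: childhood %.3f, adulthood %.3f (target 1)",
                var(ph$C), var(ph$A)))
message(sprintf("childhood-adulthood correlation: %.3f", cor(ph$C, ph$A)))

het <- 2 * v$eaf * (1 - v$eaf)
gv <- tapply(study$effects$gamma_child^2 * het, v$component, sum)
message(sprintf("childhood genetic variance by component: child-specific %.3f, shared %.3f",
                gv[["child"]], gv[["shared"]]))

write_tsv(v, "variant_panel.tsv")
write_truth(study, file.path(RESULTS_DIR, "truth.tsv"))
message("  wrote ", file.path(RESULTS_DIR, "truth.tsv"))

# a small dosage excerpt and matching minimal VCF demonstrate the formats
write_dosages(G[1:100, 1:20], v[1:20, ], file.path(RESULTS_DIR, "excerpt"),
              ids = study$exposure$ids[1:100])
write_minimal_vcf(G[1:100, 1:20], v[1:20, ],
                  file.path(RESULTS_DIR, "excerpt.vcf"),
                  ids = study$exposure$ids[1:100])
message("  wrote dosage + VCF excerpts under ", RESULTS_DIR)

cohort_summary <- data.frame(
  cohort = c("exposure", "outcome"),
  n = c(nrow(G), nrow(study$outcome$genotypes)),
  var_childhood = c(var(ph$C), var(study$outcome$phenotypes$C)),
  var_adulthood = c(var(ph$A), var(study$outcome$phenotypes$A)),
  cor_child_adult = c(cor(ph$C, ph$A),
                      cor(study$outcome$phenotypes$C, study$outcome$phenotypes$A))
)
write_tsv(cohort_summary, "cohort_summary.tsv")
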