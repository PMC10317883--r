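#!/usr/bin/env Rscript
# Monte-Carlo evaluation of the estimators under the default study design:
# (i) parameter recovery - do the MVMR direct effects centre on the
# configured truth, with honest confidence intervals? (ii) path tracing -
# does the univariable childhood estimate converge to
# theta_child + phi * theta_adult while the MVMR direct effect removes the
# phi path? (iii) the size of the MR-Egger intercept test without
# pleiotropy. 100 replicates per experiment.

source("analysis/_common.R")

R <- 100

message("parameter recovery (theta_child = -0.05, theta_adult = +0.15), ", R, " replicates ...")
rec <- replicate_study(recovery_config(theta_child = -0.05, theta_adult = 0.15),
                       n_replicates = R, seed = sub_seed(SEED, 1), quiet = FALSE)
s <- rec$summary
mv <- s[s$method == "MVMR", ]
for (i in seq_len(nrow(mv))) {
  message(sprintf("  MVMR %-9s truth %+0.3f: mean %+0.4f (bias %+0.4f, empirical SE %.4f), 95%% CI coverage %.3f",
                  mv$exposure[i], mv$reference[i], mv$mean_estimate[i],
                  mv$bias[i], mv$empirical_se[i], mv$coverage[i]))
}

message("path-tracing attenuation (theta_child = 0, phi = 0.5, theta_adult = 0.2), ", R, " replicates ...")
att <- replicate_study(attenuation_config(phi = 0.5, theta_adult = 0.2),
                       n_replicates = R, seed = sub_seed(SEED, 2), quiet = FALSE)
sa <- att$summary
uni <- sa[sa$method == "IVW" & sa$exposure == "childhood", ]
mvc <- sa[sa$method == "MVMR" & sa$exposure == "childhood", ]
message(sprintf("  univariable childhood IVW: mean %+0.4f (path-traced value 0.100)", uni$mean_estimate))
message(sprintf("  MVMR childhood direct:     mean %+0.4f (true direct effect 0)", mvc$mean_estimate))

message("MR-Egger intercept test under the no-pleiotropy null (200 replicates) ...")
enull <- egger_null_rejection(n_variants = 50, n_replicates = 200,
                              seed = sub_seed(SEED, 3))
message(sprintf("  rejection rate at alpha = 0.05: %.3f", enull$rejection_rate))

out <- rbind(
  cbind(experiment = "recovery", rec$summary),
  cbind(experiment = "attenuation", att$summary)
)
write_tsv(out, "replication_summary.tsv")
write_tsv(data.frame(experiment = "egger_null",
                     n_replicates = enull$n_replicates,
                     rejection_rate_05 = enull$rejection_rate,
                     mean_intercept = enull$mean_intercept),
          "egger_null.tsv")
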