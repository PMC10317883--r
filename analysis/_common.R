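# Shared settings for the numbered analysis scripts. Every script derives
# all randomness from this one master seed, so any script can be re-run in
# isolation and reproduce its tables byte for byte.

suppressMessages(library(lifecourseMR))

SEED <- 42L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

CFG <- default_config()

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  message("  wrote ", path)
  path
}
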