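# Shared configuration for the analysis drivers: one seeded synthetic
# drinking-water-like study with a disinfected and a non-disinfected arm.
# All scripts are deterministic; rerunning reproduces identical tables.

library(aquaphage)

STUDY_SEED <- 20260928 %% 2147483647L
RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")

study_config <- function() {
  synthetic_config(
    n_genera = 8L, contigs_per_genus = 5L,
    n_viral_contigs = 30L,
    n_samples_per_condition = 6L,
    reads_per_sample = 20000L,
    seed = as.integer(STUDY_SEED))
}

study_community <- function() generate_community(study_config())

save_table <- function(df, name) {
  dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(RESULTS_DIR, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
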