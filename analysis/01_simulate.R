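#!/usr/bin/env Rscript
# Simulate the discovery and replication cohorts, apply QC and mean
# imputation, and record what was planted. Raw cohort dumps go to scratch/
# (regenerable from the seeds in settings.R); the summary table to results/.

source("analysis/settings.R")

summaries <- list()
for (which in c("discovery", "replication")) {
  coh <- make_cohort(which)
  summaries[[which]] <- data.frame(
    cohort = which,
    n_subjects = nrow(coh$stack$values),
    n_nodes = coh$stack$N,
    n_edges = edge_count(coh$stack$N),
    age_mean = round(mean(coh$subjects$age), 1),
    age_min = round(min(coh$subjects$age), 1),
    age_max = round(max(coh$subjects$age), 1),
    pct_female = round(100 * mean(coh$subjects$sex), 1))

  dir <- file.path(SCRATCH_DIR, "cohorts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_connectome_long(coh$stack, file.path(dir, paste0(which, "_connectome.csv")))
  write_covariates(coh$subjects, file.path(dir, paste0(which, "_covariates.csv")))
}
write_parcellation(synthetic_parcellation(N_NODES),
                   file.path(SCRATCH_DIR, "cohorts", "parcellation.csv"))

tab <- do.call(rbind, summaries)
write.csv(tab, file.path(RESULTS_DIR, "cohort_summary.csv"), row.names = FALSE)
print(tab, row.names = FALSE)

truth <- planted_truth(generate_cohort(study_spec(), seed = SEED_DISCOVERY))
jsonlite::write_json(truth, file.path(RESULTS_DIR, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("planted: subnetwork A = %d regions (mediated chain), subnetwork B = %d regions (-0.004 z/yr)\n",
            length(PLANT_A), length(PLANT_B)))
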