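#!/usr/bin/env Rscript
# Edge-wise regression of every connectivity edge on age (sex- and
# confound-adjusted) in both cohorts; summarises the age t-statistics inside
# and outside the planted subnetworks and the quadratic-term decision.

source("analysis/settings.R")

rows <- list()
for (which in c("discovery", "replication")) {
  coh <- make_cohort(which)
  f <- fit_cohort(coh)
  fits <- f$fits
  eids_A <- agenet:::intra_edges(PLANT_A, N_NODES)
  eids_B <- agenet:::intra_edges(PLANT_B, N_NODES)
  bg <- setdiff(seq_len(nrow(fits)), c(eids_A, eids_B))
  rows[[which]] <- data.frame(
    cohort = which,
    used_quadratic = any(fits$used_quadratic),
    mean_t_subnet_A = mean(fits$t_age[eids_A]),
    mean_t_subnet_B = mean(fits$t_age[eids_B]),
    mean_t_background = mean(fits$t_age[bg]),
    frac_bg_p05 = mean(fits$p_age[bg] < 0.05),
    n_sig_neg_edges = sum(fits$p_age < 0.05 & fits$t_age < 0))
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(RESULTS_DIR, "edge_regression_summary.csv"), row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)

cat("\nThe t-statistics of the age effect centre near zero on background edges\n")
cat("(~5% nominally significant) and are strongly negative inside both planted\n")
cat("subnetworks, so the -log10(p) inference matrix carries the planted blocks.\n")
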