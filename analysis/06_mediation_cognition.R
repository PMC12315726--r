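#!/usr/bin/env Rscript
# Path analysis on the discovery cohort: how much of the age-related decline
# in mean subnetwork connectivity runs through white-matter FA and through
# log WMH volume, and how subnetwork connectivity relates to the general
# cognitive score (PC1 of the nine-assessment battery) controlling for age.

source("analysis/settings.R")

coh <- make_cohort("discovery")
ex <- extract_subnetworks(fit_cohort(coh)$W)
truth <- generate_cohort(study_spec(), seed = SEED_DISCOVERY)$truth

med_rows <- cog_rows <- list()
score <- cognitive_score(coh$subjects[, paste0("cog", 1:9)], seed = 3001)
cat(sprintf("cognitive PC1 explains %.1f%% of battery variance\n\n",
            100 * attr(score, "explained_variance")))

for (k in seq_along(ex$subnetworks)) {
  s <- ex$subnetworks[[k]]
  mr <- mean_subnetwork_rsfc(coh$stack, s$nodes)
  for (m in c("fa", "log_wmh")) {
    fit <- fit_mediation(coh$subjects$age, coh$subjects[[m]], mr,
                         coh$subjects$sex, n_boot = 1000, seed = 4001)
    med_rows[[paste(k, m)]] <- data.frame(
      rank = k, mediator = m,
      a = fit$a, b = fit$b, c_prime = fit$c_prime,
      prop_mediated_pct = 100 * fit$prop_mediated,
      ci_low_pct = 100 * fit$ci[1], ci_high_pct = 100 * fit$ci[2],
      p_indirect = fit$p_indirect)
  }
  ca <- cognitive_association(score, mr, coh$subjects$age)
  cog_rows[[k]] <- data.frame(rank = k, coefficient = ca$coefficient,
                              ci_low = ca$ci[1], ci_high = ca$ci[2],
                              p_value = ca$p_value)
}
med <- do.call(rbind, med_rows)
cog <- do.call(rbind, cog_rows)
write.csv(med, file.path(RESULTS_DIR, "mediation.csv"), row.names = FALSE)
write.csv(cog, file.path(RESULTS_DIR, "cognition.csv"), row.names = FALSE)
print(med, row.names = FALSE, digits = 3)
cat("\n")
print(cog, row.names = FALSE, digits = 3)

imp <- truth$implied
cat(sprintf("\nGenerator-implied proportions for the mediated subnetwork: FA %.1f%%, WMH %.1f%%.\n",
            100 * imp$prop_mediated_fa, 100 * imp$prop_mediated_wmh))
cat("The rank-1 (mediated) subnetwork's estimates should bracket these; the\n")
cat("plain-decline subnetwork shows no appreciable mediated share.\n")
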