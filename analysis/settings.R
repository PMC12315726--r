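# Shared study settings for the analysis scripts. Each numbered script is
# self-contained: it regenerates the synthetic cohorts from these fixed seeds
# (generation is cheap and bit-reproducible) rather than reading intermediate
# files. Summary tables land in results/; bulky raw cohort dumps in scratch/.

library(agenet)

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)

# Two cohorts emulating a discovery and an independent replication sample:
# same planted structure, independent noise and subjects.
# - subnetwork A: 12 regions, age effect delivered through the white-matter
#   mediation chain (direct + FA + WMH paths)
# - subnetwork B: 6 regions, plain -0.004 z/yr decline
N_NODES <- 90L
PLANT_A <- 0:11
PLANT_B <- 40:45

study_spec <- function(n_subjects = 300L) {
  cohort_spec(
    n_subjects = n_subjects, n_nodes = N_NODES,
    planted = list(planted_subnetwork(PLANT_A),
                   planted_subnetwork(PLANT_B, beta_age = -0.004)),
    noise_sd = 0.3, missing_rate = 0.01,
    mediation = mediation_spec(),       # a_fa=-0.5 b_fa=0.4 a_wmh=0.55 b_wmh=-0.35 c'=-0.8
    cog_missing_rate = 0.02)
}

SEED_DISCOVERY <- 101L
SEED_REPLICATION <- 202L
M_PERM <- 199L

make_cohort <- function(which = c("discovery", "replication")) {
  which <- match.arg(which)
  seed <- if (which == "discovery") SEED_DISCOVERY else SEED_REPLICATION
  coh <- generate_cohort(study_spec(), seed = seed)
  coh$stack <- impute_missing(suppressMessages(qc_filter(coh$stack)))
  coh$subjects <- coh$subjects[match(coh$stack$subject_ids, coh$subjects$subject_id), ]
  coh
}

fit_cohort <- function(coh) {
  fits <- fit_edges(coh$stack, coh$subjects, include_quadratic = "auto")
  list(fits = fits, W = build_inference_matrix(fits, direction = "negative"))
}
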