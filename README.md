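# agenet

Data-driven dense subnetwork analysis of aging functional connectomes.

## The problem

Resting-state functional connectivity (rsFC) — the Fisher z-transformed
correlation of BOLD signal between pairs of atlas regions — declines with age
in specific parts of the brain, but analyses confined to predefined
functional networks miss age-related edges that cross network boundaries and
over-call networks in which only a few edges carry an effect. `agenet`
implements the data-driven alternative for researchers studying brain aging
at cohort scale:

1. **Edge-wise regression.** Every one of the N(N−1)/2 edges (30,135 for a
   246-region atlas) is regressed on age, sex, and five imaging confounds:
   `E(Y_ij) = β0 + β1·age (+ β2·age²) + β3·sex + β4..8·confounds`, with the
   quadratic term kept only when significant with partial r² ≥ 1%. The
   −log10 p-values of the age effect form a weighted inference matrix
   `W = {−log10 p_ij}` (age-related *decreases* by default).
2. **Dense subnetwork extraction.** Node sets S maximizing the shrunken
   score `T(G(S)) = Σ_{i<j∈S} (w_ij − λ)` are extracted greedily with local
   refinement and peel-off; the per-edge penalty λ (default −log10 0.05) is
   an l0-style shrinkage that rejects sparse or weak subsets. An exhaustive
   oracle validates the greedy on small graphs.
3. **Max-statistic permutation inference.** Ages are permuted, the whole
   regression + extraction pipeline re-run, and each observed subnetwork is
   tested against the per-permutation maximum scores:
   `p = (1 + #{T_k ≥ T_obs}) / (M + 1)` — family-wise error control at the
   network level.
4. **Interpretation.** Extracted subnetworks are mapped onto predefined
   functional networks, hub regions (age-related edges to *all* other
   members) are flagged, and cross-cohort replication is scored by node-set
   overlap and Jaccard index.
5. **Path analysis.** Linear mediation models (age → white-matter FA → rsFC;
   age → log WMH volume → rsFC, sex-adjusted) with bootstrap CIs for the
   proportion mediated, plus the association between mean subnetwork rsFC
   and a general cognitive score (PC1 of a nine-assessment battery, PMM
   imputation) controlling for age.

A synthetic-cohort generator (`generate_cohort()`) produces cohorts with
planted age-related subnetworks, mediation chains, and a latent-factor
cognitive battery, so the entire pipeline is testable without access to
population imaging data.

## Worked example

```r
library(agenet)

spec <- cohort_spec(n_subjects = 500, n_nodes = 90,
                    planted = list(planted_subnetwork(0:11)),   # 12-node decline
                    noise_sd = 0.3,
                    mediation = mediation_spec(a_fa = -0.5, b_fa = 0.4,
                                               a_wmh = 0, b_wmh = 0, c_prime = -0.8))
coh   <- generate_cohort(spec, seed = 1)
stack <- impute_missing(coh$stack)
fits  <- fit_edges(stack, coh$subjects)
W     <- build_inference_matrix(fits, direction = "negative")
ex    <- extract_subnetworks(W)
null  <- build_null(stack, coh$subjects, M = 199, seed = 2)
ex    <- add_pvalues(ex, null)
print(ex)
#> extraction_result: 1 subnetwork(s) at lambda = 1.301
#>   [1] subnetwork: 12 nodes, score 154.143, density 0.970 (64 significant edges), permutation p = 0.005

ex$subnetworks[[1]]$nodes
#> [1]  0  1  2  3  4  5  6  7  8  9 10 11

mr  <- mean_subnetwork_rsfc(stack, ex$subnetworks[[1]]$nodes)
med <- fit_mediation(coh$subjects$age, coh$subjects$fa, mr,
                     coh$subjects$sex, n_boot = 500, seed = 3)
print(med)
#> mediation: a = -0.0425, b = 0.0179, c' = -0.0037
#>   indirect = -0.0008, total = -0.0045
#>   proportion mediated = 16.9% (95% bootstrap CI [12.8% 21.5%]), p_indirect = 0.003992
```

The extractor recovers exactly the 12 planted regions as one dense
subnetwork (97% of its intra-edges significant). Its score beats all 199
permutation maxima, giving the smallest attainable add-one p-value,
1/200 = 0.005. The path model attributes 16.9% of the age-related decline in
mean subnetwork connectivity to the FA pathway — the generating chain
implies 20% (`a·b/(a·b + c') = 0.2/1.0`), inside the bootstrap CI.

`run_pipeline()` executes all of the above from one config (list or YAML),
with a single master seed fanned out per stage, and `compare_cohorts()`
summarizes cross-cohort replication. The numbered scripts under `analysis/`
are a complete two-cohort (discovery + replication) study over the package:
simulation, edge regression, extraction, permutation inference, network
mapping, and mediation/cognition, each writing its tables to `results/`.

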