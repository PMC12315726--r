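---
title: "Dense age-related subnetworks in the functional connectome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense age-related subnetworks in the functional connectome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agenet)
```

## The problem

Resting-state functional connectivity (rsFC) — the Fisher z-transformed
Pearson correlation of BOLD time series between pairs of atlas regions —
reorganizes with age. Analyses restricted to predefined functional networks
(e.g. the canonical seven resting-state networks) can both miss age-related
edges that straddle network boundaries and flag a whole network when only a
few of its edges carry an effect. `agenet` implements the data-driven
alternative: test every edge, let the age-related edges consolidate into
*dense* subnetworks discovered from the data, attach a family-wise p-value to
each discovery by a max-statistic permutation test, and only then interpret
the discoveries against the predefined networks.

## Edge-wise regression and the inference matrix

For an atlas of $N$ regions there are $N(N-1)/2$ edges (30,135 at $N = 246$).
Each edge value $Y_{ij}$ is regressed, with an identity link, on age, sex and
five imaging confounds (mean framewise displacement and four scanner/table
position measures):

$$ E(Y_{ij}) = \beta_{0,ij} + \beta_{1,ij}\,\mathrm{age} +
   \beta_{2,ij}\,\mathrm{age}^2 + \beta_{3,ij}\,\mathrm{sex} +
   \beta_{4..8,ij}\,\mathrm{confounds}. $$

All edges share one design matrix, so the whole connectome is fit with a
single factorization (`fit_edges()`); tests verify agreement with per-edge
`lm()` fits to $10^{-8}$. Age is centered before fitting — this leaves the
linear slope and its t-statistic untouched and, when the quadratic term is
present, makes $\beta_1$ the slope at the mean age. The quadratic term is
retained only when it is significant *and* non-trivial (partial $r^2 \ge$ 1%).
Because that rule is phrased for "the quadratic term" of the model rather
than edge by edge, the default applies one global decision from the median
p-value and median partial $r^2$ across edges; a per-edge mode exists
(`quad_scope = "per_edge"`).

The inference matrix is $W = \{-\log_{10} p_{ij}\}$ of the age effect, with
the sign matrix of $\hat\beta_1$ kept alongside. The default direction mask
zeroes entries with $\hat\beta_1 \ge 0$, targeting age-related *decreases*;
increases can be studied with `direction = "positive"`. Underflowing
p-values are capped at $w = 50$ so downstream arithmetic stays finite.

## Dense subnetwork extraction

The target is a clique-forming subgraph $G(S)$ that includes as many
high-weight edges as possible while shrinking away non-age-related edges.
The objective implemented here is the additive-penalty surrogate

$$ T(G(S)) = \sum_{i<j \in S} (w_{ij} - \lambda), $$

an $\ell_0$-style shrinkage: each admitted edge pays a fixed price
$\lambda$, so a subset scores positively only when its intra-edge weights
beat $\lambda$ on average. The cited extraction machinery in the source
literature is described by its goals rather than a formula; this surrogate
was chosen because it makes $\lambda$ an interpretable edge-level
significance floor (default $\lambda = -\log_{10} 0.05 \approx 1.301$) and
is exactly checkable against exhaustive enumeration on small graphs.

`extract_subnetworks()` proceeds greedily: seed at the strongest remaining
edge (edge seeding suits the clique-forming target better than node-strength
seeding), add the node with the best score gain while positive, then refine
with single-node removal / addition / swap passes until no move improves
$T$. Several top seed edges are examined per round (`n_restarts = 5`) and the
best acceptable result kept. Accepted subnetworks must have at least
`min_size = 5` nodes — smaller sets are dominated by the permutation null —
and their nodes are then *peeled off* (rows/columns zeroed), which enforces
disjoint discoveries. All tie-breaks are deterministic (lowest node id), so
extraction is a pure function of $W$.

`brute_force_best_subgraph()` scores every subset of up to 15 nodes and is
the validation oracle: on random 10–14-node instances the greedy attains the
exact optimum in well over 80% of cases and at least 95% of the optimal
score always (asserted in the tests — a documented heuristic guarantee, not
a proof).

## Max-statistic permutation inference

Ages are permuted across subjects (connectomes, sex and confounds stay
attached to their subjects — a Draper–Stoneman-style scheme that tests the
age effect conditional on the observed covariate structure; Freedman–Lane
residual permutation is available as an option). For each permutation the
regression, masking and extraction are re-run identically and
$T_k$ is the maximum extracted score (0 when nothing is extracted). Each
observed subnetwork is tested against this one null of maxima,

$$ p = \frac{1 + \#\{T_k \ge T_{obs}\}}{M + 1}, $$

which controls the family-wise error rate; the add-one estimator avoids
zero p-values at finite $M$ (smallest attainable value $1/(M+1)$; the
default $M = 1000$ resolves "p < 0.001").

A note on calibration under the defaults: with `min_size = 5` and
$\lambda = 1.3$, a null connectome essentially never yields *any*
positive-score subnetwork of that size — the false-positive probability of a
dense subnetwork decays exponentially in its size and density — so the test
at defaults is strictly conservative (the max statistic is an atom at 0).
The calibration study in the test suite therefore runs extraction at
`min_size = 2`, where the max statistic is continuous and exchangeability is
actually exercised; measured family-wise error sits at its nominal 5% level.

## Interpretation and replication

`map_to_predefined()` tallies a discovered node set against the
parcellation's predefined networks (counts and fraction of each network
captured). `identify_hubs()` flags members whose age-related edges reach a
`coverage_min` fraction of the other members (default 1: connected to *all*
of them, the strictest reading of a hub). Cross-cohort replication is scored
on node sets (`replication_overlap()`: intersection and Jaccard), with a
hypergeometric overlap p-value offered as a simple enrichment summary — the
package's own construction, not the joint false-positive probability of the
source literature, whose formula lives in cited prior work.

## Path analysis and cognition

For each subnetwork, per-subject mean intra-subnetwork rsFC is the outcome
of two linear path models (age → FA → rsFC, age → log-WMH → rsFC), adjusted
for sex. A just-identified linear path model is exactly equivalent to two
nested OLS fits, so the package estimates it that way rather than through a
general SEM optimizer: `a` from `mediator ~ age + sex`, `b` and `c'` from
`outcome ~ age + mediator + sex`. The identity
$\text{total} = ab + c'$ holds exactly (it equals the reduced-model age
coefficient; asserted to $10^{-10}$). The proportion mediated $ab/(ab+c')$
is reported on the percent scale; with both paths negative the proportion is
positive. Uncertainty comes from a subject-resampling bootstrap (percentile
CI, add-one two-sided p for the indirect effect), with a delta-method CI
reported alongside; when the total effect is near zero the proportion is
flagged unstable rather than suppressed.

The general cognitive score is the first principal component of the
standardized nine-assessment battery — chosen over a fitted factor model
because a one-factor battery makes PC1 and the factor estimate equivalent up
to scaling, and PC1 is deterministic; the explained-variance fraction
(≈70% under the default loadings) is always reported. Missing assessments
are imputed by single-draw predictive mean matching (linear predictor on the
other assessments, 5 donors, seeded draw); multiple imputation is out of
scope. The rsFC–cognition association is `score ~ mean_rsfc + age`.

## The synthetic cohort generator

`generate_cohort()` produces cohorts with exactly the structure the analysis
assumes: ages uniform on 44–82 years (the uniform rather than an empirical
age distribution — covariate design matters only through leverage), sex
Bernoulli(0.5), standard-normal confounds, Gaussian edge noise
(SD 0.3 by default), per-edge intercepts near 0.25 z, and planted node
subsets whose intra-subset edges decline linearly in age
(−0.003 z/yr by default — at $n = 300$ this gives per-edge $t \approx -1.9$,
a realistically faint single-edge signal that only the network-level
analysis aggregates into certainty). Age effects are applied to centered age
in z-units *per year*; the mediation chain operates on standardized age and
unit-scale mediators so its path coefficients are directly interpretable,
with a configurable edge-scale (proportions mediated are invariant to it).
When a mediation spec is present, the first planted subnetwork's age effect
is generated entirely by the chain (direct path plus FA and WMH paths) so
that the implied proportion mediated, $ab/(ab+c')$ per mediator, holds in
expectation; its `beta_age` is ignored to avoid double-counting. The
cognitive battery loads on one latent factor (loadings 0.814, giving ≈70%
PC1 variance) correlated with the first subnetwork's mean connectivity.
Edge missingness is completely at random.

What the generator does *not* emulate: spatial autocorrelation of parcels,
heavy-tailed or heteroscedastic edge noise, empirical age distributions,
site/scanner batch structure, or raw BOLD time series. Passing tests
therefore demonstrate correctness of the machinery under the assumed model,
not robustness to real-data violations of it.

## Numerical choices and degenerate inputs

* Correlations at $|r| \ge 1$ are clipped to $1 - 10^{-7}$ before the
  Fisher transform; zero-variance time-series columns yield missing edges.
* QC defaults (missing ratio ≤ 0.1, per-subject edge SD in [0.01, 2]) are
  placeholders for cohort-specific thresholds and are configurable.
* Edges with zero residual variance get $t = 0$, $p = 1$ with a warning;
  rank-deficient designs error naming the collinear columns.
* All stochastic steps (generator, permutations, bootstrap, PMM) take
  explicit seeds; `run_pipeline()` fans one master seed out to the stages
  through fixed offsets and logs them.

## Problem sizes used in the tests

The simulation studies in the test suite use: the planted-recovery spec
(12 nodes, −0.003 z/yr, $n = 500$, $N = 90$, 50 seeds), the headline
inference run ($n = 300$, $N = 90$, $M = 999$), family-wise calibration
(200 null cohorts at $n = 200$, $N = 60$, $M = 99$, extraction at
`min_size = 2` as discussed above), mediation recovery at $n = 5000$ with
CI coverage over 200 replicates at $n = 1000$, and null-uniformity checks
over 20 seeds at $n = 150$, $N = 40$. These sizes make every property
measurable with meaningful Monte-Carlo precision while keeping the full
suite comfortably reproducible on a laptop.

## Known limitations

* The additive-penalty objective is this package's explicit surrogate for
  the extraction tools cited in the source literature; their exact objective
  and stopping rule are not public, so score values are not comparable
  across implementations (node sets and inference are).
* Greedy extraction carries a heuristic, test-asserted guarantee, not an
  optimality proof; adversarial weight patterns can defeat it.
* Cross-sectional only: nothing here separates aging from cohort effects.
* The hypergeometric replication p-value ignores extraction's selection
  effects; treat it as descriptive.
* Edge-level multiplicity (e.g. FDR on single edges) is deliberately absent:
  inference is at the network level.
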