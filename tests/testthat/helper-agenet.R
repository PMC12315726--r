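# Shared fixture builders. Everything is generated in code; no data files.

# A weight matrix with one planted dense block on noisy background.
make_planted_W <- function(N, block, w_in = 3, bg_sd = 0.3, seed = 1) {
  agenet:::with_seed(seed, {
    W <- matrix(abs(stats::rnorm(N * N, 0, bg_sd)), N, N)
    W[upper.tri(W)] <- t(W)[upper.tri(W)]
    W <- (W + t(W)) / 2
    W[block + 1L, block + 1L] <- w_in
    diag(W) <- 0
    W
  })
}

# Null-style weights: w = -log10(U(0,1)) per edge (half zeroed to mimic the
# direction mask).
make_null_W <- function(N, seed = 1, masked = TRUE) {
  agenet:::with_seed(seed, {
    w <- -log10(stats::runif(agenet::edge_count(N)))
    if (masked) w[stats::runif(length(w)) < 0.5] <- 0
    agenet:::edges_to_matrix(w, N)
  })
}

# A tiny complete stack + covariate table with iid N(0, sd) edges.
make_null_cohort <- function(n = 50, N = 10, sd = 0.3, seed = 1) {
  agenet::generate_cohort(
    agenet::cohort_spec(n_subjects = n, n_nodes = N, planted = list(),
                        noise_sd = sd),
    seed = seed)
}

# Hand-built edge_fits table with given p-values and age-coefficient signs.
make_fits <- function(p, sgn, N) {
  idx <- agenet::edge_index(N)
  structure(data.frame(idx, beta0 = 0, beta_age = sgn, beta_age_sq = NA_real_,
                       t_age = sgn * 2, p_age = p,
                       partial_r2_agesq = NA_real_, used_quadratic = FALSE),
            class = c("edge_fits", "data.frame"), N = N)
}
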