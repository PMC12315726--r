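# Synthetic cohorts with the statistical structure the downstream analysis
# assumes: planted node subsets whose intra-subset edges decline linearly with
# age, global confound/sex effects, an age -> white-matter -> connectivity
# mediation chain, and a nine-assessment cognitive battery loading on one
# latent factor tied to subnetwork connectivity.

#' Describe a planted age-related subnetwork
#'
#' @param nodes Integer vector of 0-based node ids (at least 2).
#' @param beta_age Per-edge linear age effect on intra-subset edges, in
#'   Fisher-z units per year (typically negative).
#' @param beta_age_sq Optional quadratic age effect (per year^2, on centered
#'   age).
#' @param hub_nodes Optional subset of `nodes` whose edges to every other
#'   member are guaranteed to carry the age effect (they already do for a
#'   fully planted set; the field exists to mark intended hubs in the truth).
#' @return A `planted_subnetwork` spec.
#' @export
planted_subnetwork <- function(nodes, beta_age = -0.003, beta_age_sq = 0,
                               hub_nodes = integer(0)) {
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) < 2L) stop_invalid("a planted subnetwork needs >= 2 nodes")
  if (!all(hub_nodes %in% nodes)) stop_invalid("hub_nodes must be a subset of nodes")
  structure(list(nodes = nodes, beta_age = beta_age, beta_age_sq = beta_age_sq,
                 hub_nodes = sort(unique(as.integer(hub_nodes)))),
            class = "planted_subnetwork")
}

#' Mediation path coefficients for the synthetic generator
#'
#' Paths operate on the standardized-age scale with (approximately) unit-scaled
#' mediators, so `a*b / (a*b + c_prime)` is the proportion of the age effect on
#' subnetwork connectivity carried through a single mediator. `edge_scale`
#' converts the path outcome onto the Fisher-z edge scale; proportions are
#' invariant to it.
#'
#' @param a_fa,b_fa Age -> FA and FA -> connectivity paths.
#' @param a_wmh,b_wmh Age -> log-WMH and log-WMH -> connectivity paths.
#' @param c_prime Direct age -> connectivity path.
#' @param edge_scale Fisher-z units per standardized path unit.
#' @return A `mediation_spec`.
#' @export
mediation_spec <- function(a_fa = -0.5, b_fa = 0.4, a_wmh = 0.55, b_wmh = -0.35,
                           c_prime = -0.8, edge_scale = 0.05) {
  structure(list(a_fa = a_fa, b_fa = b_fa, a_wmh = a_wmh, b_wmh = b_wmh,
                 c_prime = c_prime, edge_scale = edge_scale),
            class = "mediation_spec")
}

#' Full synthetic-cohort specification
#'
#' Defaults emulate the study conditions the pipeline targets: ages uniform on
#' 44-82 years, one planted 12-node subnetwork with a -0.003 z/yr intra-edge
#' decline, Gaussian edge noise of SD 0.3, and cognitive loadings chosen so the
#' first principal component of the battery explains about 70% of its variance.
#'
#' @param n_subjects Cohort size.
#' @param n_nodes Atlas size N.
#' @param age_range Uniform age range in years.
#' @param planted List of [planted_subnetwork()] specs (may be empty).
#' @param noise_sd Edge-level Gaussian noise SD (z units).
#' @param baseline_mean,baseline_sd Distribution of per-edge intercepts.
#' @param confound_betas Length-5 effects of the standard-normal imaging
#'   confounds on every edge.
#' @param sex_beta Effect of sex (0/1) on every edge.
#' @param missing_rate Completely-at-random edge missingness fraction.
#' @param mediation `NULL` or a [mediation_spec()]; when present, the FIRST
#'   planted subnetwork's age effect is generated by the mediation chain
#'   (direct path `c_prime` plus indirect paths through FA and log-WMH) and its
#'   `beta_age` is ignored.
#' @param cog_loadings Length-9 loadings of the cognitive battery on one
#'   latent factor (default 0.814 each, giving ~70% PC1 variance).
#' @param cog_rsfc_cor Correlation between the latent cognitive factor and the
#'   (standardized) mean connectivity of the first planted subnetwork.
#' @param cog_missing_rate MCAR missingness in the battery.
#' @param seed Default seed used by [generate_cohort()].
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 300, n_nodes = 90, age_range = c(44, 82),
                        planted = list(planted_subnetwork(0:11)),
                        noise_sd = 0.3, baseline_mean = 0.25, baseline_sd = 0.05,
                        confound_betas = rep(0.002, 5), sex_beta = 0.01,
                        missing_rate = 0, mediation = NULL,
                        cog_loadings = rep(0.814, 9), cog_rsfc_cor = 0.3,
                        cog_missing_rate = 0, seed = NULL) {
  stopifnot(n_subjects >= 2, n_nodes >= 2, length(age_range) == 2,
            age_range[1] < age_range[2], noise_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            length(confound_betas) == 5, length(cog_loadings) == 9,
            abs(cog_rsfc_cor) <= 1, all(abs(cog_loadings) <= 1))
  for (p in planted) {
    if (!inherits(p, "planted_subnetwork")) stop_invalid("planted entries must be planted_subnetwork specs")
    if (any(p$nodes >= n_nodes)) {
      stop(structure(class = c("agenet_invalid_spec", "error", "condition"),
                     list(message = "planted node id out of range", call = sys.call())))
    }
  }
  if (!is.null(mediation)) {
    stopifnot(inherits(mediation, "mediation_spec"))
    if (length(planted) == 0L) stop_invalid("mediation requires at least one planted subnetwork")
  }
  structure(list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
                 age_range = age_range, planted = planted, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 confound_betas = confound_betas, sex_beta = sex_beta,
                 missing_rate = missing_rate, mediation = mediation,
                 cog_loadings = cog_loadings, cog_rsfc_cor = cog_rsfc_cor,
                 cog_missing_rate = cog_missing_rate, seed = seed),
            class = "cohort_spec")
}

# Edge positions (1-based) of all intra-subset pairs of `nodes` (0-based).
intra_edges <- function(nodes, N) {
  if (length(nodes) < 2L) return(integer(0))
  prs <- utils::combn(sort(nodes), 2)
  pair_to_edge(prs[1, ], prs[2, ], N)
}

#' Generate a synthetic cohort
#'
#' Draws ages uniformly, sex Bernoulli(0.5), standard-normal imaging
#' confounds, and edge values `beta0 + effects + N(0, noise_sd^2)` where the
#' age effect is `beta_age` (per year, on centered age) inside planted
#' intra-subset edges and zero elsewhere. See [cohort_spec()] for the
#' mediation and cognition chains. Identical seeds give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A list of class `synthetic_cohort`: `stack`
#'   ([connectome_stack()]), `subjects` (covariate table), and `truth` (the
#'   planted structure; see [planted_truth()]).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  with_seed(seed, {
    n <- spec$n_subjects; N <- spec$n_nodes; E <- edge_count(N)
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    age_c <- age - mean(age)
    age_std <- age_c / stats::sd(age)
    sex <- stats::rbinom(n, 1, 0.5)
    conf <- matrix(stats::rnorm(n * 5), n, 5,
                   dimnames = list(NULL, paste0("conf", 1:5)))
    beta0 <- stats::rnorm(E, spec$baseline_mean, spec$baseline_sd)
    values <- matrix(stats::rnorm(n * E, 0, spec$noise_sd), n, E)
    values <- sweep(values, 2, beta0, "+")
    values <- values + as.vector(conf %*% spec$confound_betas) +
      spec$sex_beta * sex

    med <- spec$mediation
    planted_edges <- lapply(spec$planted, function(p) intra_edges(p$nodes, N))
    for (k in seq_along(spec$planted)) {
      if (!is.null(med) && k == 1L) next  # age effect comes from the chain
      p <- spec$planted[[k]]
      values[, planted_edges[[k]]] <- values[, planted_edges[[k]]] +
        (p$beta_age * age_c + p$beta_age_sq * age_c^2)
    }

    # white-matter mediators (standardized scale)
    if (!is.null(med)) {
      fa <- med$a_fa * age_std + sqrt(max(0, 1 - med$a_fa^2)) * stats::rnorm(n)
      log_wmh <- med$a_wmh * age_std + sqrt(max(0, 1 - med$a_wmh^2)) * stats::rnorm(n)
      chain <- med$edge_scale *
        (med$c_prime * age_std + med$b_fa * fa + med$b_wmh * log_wmh)
      values[, planted_edges[[1]]] <- values[, planted_edges[[1]]] + chain
    } else {
      fa <- stats::rnorm(n)
      log_wmh <- stats::rnorm(n)
    }

    # cognitive battery: one latent factor, tied to subnetwork connectivity
    if (length(planted_edges) > 0L) {
      mr <- rowMeans(values[, planted_edges[[1]], drop = FALSE])
      mr_std <- as.vector(scale(mr))
      rho <- spec$cog_rsfc_cor
      latent <- rho * mr_std + sqrt(1 - rho^2) * stats::rnorm(n)
    } else {
      latent <- stats::rnorm(n)
    }
    battery <- vapply(spec$cog_loadings, function(l) {
      l * latent + sqrt(1 - l^2) * stats::rnorm(n)
    }, numeric(n))
    colnames(battery) <- paste0("cog", 1:9)

    missing <- matrix(stats::runif(n * E) < spec$missing_rate, n, E)
    if (spec$cog_missing_rate > 0) {
      battery[matrix(stats::runif(n * 9) < spec$cog_missing_rate, n, 9)] <- NA_real_
    }

    subject_ids <- sprintf("sub%04d", seq_len(n))
    vals <- values; vals[missing] <- NA_real_
    stack <- connectome_stack(vals, N, subject_ids, missing)
    subjects <- as_subject_table(data.frame(
      subject_id = subject_ids, age = age, sex = sex, conf,
      fa = fa, log_wmh = log_wmh, battery))

    imp <- if (!is.null(med)) {
      tot_fa <- med$a_fa * med$b_fa
      tot_wmh <- med$a_wmh * med$b_wmh
      total <- med$c_prime + tot_fa + tot_wmh
      list(prop_mediated_fa = tot_fa / total, prop_mediated_wmh = tot_wmh / total)
    } else NULL
    truth <- list(planted = lapply(spec$planted, `[[`, "nodes"),
                  hub_nodes = lapply(spec$planted, `[[`, "hub_nodes"),
                  beta_age = vapply(spec$planted, `[[`, numeric(1), "beta_age"),
                  planted_edges = planted_edges,
                  mediation = med, implied = imp, seed = seed)
    structure(list(stack = stack, subjects = subjects, truth = truth),
              class = "synthetic_cohort")
  })
}

#' Recover the planted structure of a synthetic cohort
#'
#' @param x A `synthetic_cohort` (or its `truth` element).
#' @return List with `node_sets` (planted 0-based node sets) and `paths`
#'   (the mediation coefficients `a_fa, b_fa, a_wmh, b_wmh, c_prime`, or
#'   `NULL`).
#' @export
planted_truth <- function(x) {
  truth <- if (inherits(x, "synthetic_cohort")) x$truth else x
  paths <- truth$mediation
  list(node_sets = truth$planted,
       paths = if (is.null(paths)) NULL else
         unlist(paths[c("a_fa", "b_fa", "a_wmh", "b_wmh", "c_prime")]))
}

#' Simulate a single linear mediation chain
#'
#' `exposure ~ N(0,1)`, `mediator = a * exposure + e`, `outcome = c_prime *
#' exposure + b * mediator + e`. The implied proportion mediated is
#' `a*b / (a*b + c_prime)`.
#'
#' @param n Sample size.
#' @param a,b,c_prime Path coefficients.
#' @param sd_mediator,sd_outcome Residual SDs.
#' @param seed Optional seed.
#' @return Data frame with columns `exposure`, `mediator`, `outcome`, `sex`
#'   (Bernoulli 0.5, independent).
#' @export
simulate_mediation <- function(n, a = -0.5, b = 0.4, c_prime = -0.8,
                               sd_mediator = 1, sd_outcome = 1, seed = NULL) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    m <- a * x + stats::rnorm(n, 0, sd_mediator)
    y <- c_prime * x + b * m + stats::rnorm(n, 0, sd_outcome)
    data.frame(exposure = x, mediator = m, outcome = y,
               sex = stats::rbinom(n, 1, 0.5))
  })
}

#' Synthetic parcellation table
#'
#' Assigns the `N` nodes to predefined functional networks in contiguous
#' blocks (defaults to seven canonical resting-state network names), for use
#' with [map_to_predefined()] when no real atlas table is supplied.
#'
#' @param N Node count.
#' @param networks Character vector of network names.
#' @return A `parcellation` data.frame.
#' @export
synthetic_parcellation <- function(N, networks = c("Visual", "Somatomotor",
                                                   "DorsalAttention", "VentralAttention",
                                                   "Limbic", "Frontoparietal", "Default")) {
  net <- networks[ceiling(seq_len(N) / (N / length(networks)))]
  as_parcellation(data.frame(
    node_id = 0:(N - 1),
    label = sprintf("region_%03d", 0:(N - 1)),
    lobe = rep_len(c("frontal", "temporal", "parietal", "insular",
                     "limbic", "occipital", "subcortical"), N),
    network = net))
}
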