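# End-to-end orchestration: cohort (synthetic or from files) -> QC ->
# imputation -> edge regression -> inference matrix -> dense-subnetwork
# extraction -> max-statistic permutation p-values -> predefined-network
# mapping and hubs -> mediation and cognition. One master seed is fanned out
# to the stages through fixed offsets (see stage_seed()), so a config + seed
# pair is fully reproducible.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    cohort = list(source = "synthetic", spec = list()),
    parcellation = NULL,
    qc = list(max_missing_ratio = 0.1, variation_bounds = c(0.01, 2)),
    regression = list(include_quadratic = "auto", direction = "negative",
                      w_max = 50),
    extraction = list(lambda = default_lambda(), min_size = 5L,
                      max_subnetworks = 10L, p_thresh = 0.05, n_restarts = 5L),
    permutation = list(M = 1000L, scheme = "draper_stoneman"),
    mediation = list(enabled = TRUE, n_boot = 500L),
    out_dir = NULL
  )
}

config_error <- function(path, msg) {
  stop(structure(class = c("agenet_config_error", "error", "condition"),
                 list(message = paste0("config error at '", path, "': ", msg),
                      call = NULL)))
}

# Merge user config over defaults, rejecting unknown keys.
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("", "config must be a list or a YAML path")
  defaults <- pipeline_defaults()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) config_error(bad[1], "unknown key")
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub_bad <- setdiff(names(config[[key]]), names(defaults[[key]]))
      if (length(sub_bad) && key != "cohort") {
        config_error(paste0(key, ".", sub_bad[1]), "unknown key")
      }
      defaults[[key]] <- utils::modifyList(defaults[[key]], config[[key]])
    } else {
      defaults[[key]] <- config[[key]]
    }
  }
  if (!defaults$cohort$source %in% c("synthetic", "files")) {
    config_error("cohort.source", "must be 'synthetic' or 'files'")
  }
  defaults
}

# Build a cohort_spec from a plain config list (as parsed from YAML).
spec_from_list <- function(lst) {
  lst <- lst %||% list()
  if (!is.null(lst$planted)) {
    lst$planted <- lapply(lst$planted, function(p) {
      do.call(planted_subnetwork, p)
    })
  }
  if (!is.null(lst$mediation) && !inherits(lst$mediation, "mediation_spec")) {
    lst$mediation <- do.call(mediation_spec, lst$mediation)
  }
  do.call(cohort_spec, lst)
}

#' Run the full connectome analysis pipeline
#'
#' @param config A config list or path to a YAML file. Top-level keys (all
#'   optional, defaults shown by `agenet:::pipeline_defaults()`): `seed`,
#'   `cohort` (`source = "synthetic"` with a `spec` list passed to
#'   [cohort_spec()], or `source = "files"` with `connectome`, `covariates`,
#'   and optional `format = "long"|"matrices"`), `parcellation` (path; a
#'   synthetic block parcellation is used when omitted), `qc`, `regression`
#'   (`include_quadratic`, `direction`, `w_max`), `extraction` (`lambda`,
#'   `min_size`, `max_subnetworks`, `p_thresh`, `n_restarts`), `permutation`
#'   (`M`, `scheme`), `mediation` (`enabled`, `n_boot`), `out_dir`.
#' @return A `pipeline_report`: subnetworks with node lists, scores,
#'   densities, permutation p-values, network mappings and hubs; mediation and
#'   cognition estimates; the resolved config, stage seeds, and versions. When
#'   `out_dir` is set, a JSON report and delimited tables are written there.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  seed <- cfg$seed

  # --- cohort -------------------------------------------------------------
  truth <- NULL
  if (cfg$cohort$source == "synthetic") {
    spec <- spec_from_list(cfg$cohort$spec)
    coh <- generate_cohort(spec, seed = stage_seed(seed, "cohort"))
    stack <- coh$stack; subjects <- coh$subjects; truth <- coh$truth
  } else {
    fmt <- cfg$cohort$format %||% "long"
    if (is.null(cfg$cohort$connectome) || is.null(cfg$cohort$covariates)) {
      config_error("cohort", "source 'files' needs 'connectome' and 'covariates' paths")
    }
    stack <- switch(fmt,
                    long = read_connectome_long(cfg$cohort$connectome),
                    matrices = read_connectome_matrices(cfg$cohort$connectome),
                    config_error("cohort.format", "must be 'long' or 'matrices'"))
    subjects <- read_covariates(cfg$cohort$covariates)
  }
  parc <- if (is.null(cfg$parcellation)) synthetic_parcellation(stack$N) else
    read_parcellation(cfg$parcellation)
  if (nrow(parc) != stack$N) config_error("parcellation", "node count mismatch with connectome")

  # --- QC + imputation ----------------------------------------------------
  stack <- qc_filter(stack, cfg$qc$max_missing_ratio,
                     unlist(cfg$qc$variation_bounds), quiet = TRUE)
  subjects <- subjects[match(stack$subject_ids, subjects$subject_id), ]
  subjects <- as_subject_table(subjects)
  stack <- impute_missing(stack)

  # --- edge regression + inference matrix ----------------------------------
  fits <- fit_edges(stack, subjects,
                    include_quadratic = cfg$regression$include_quadratic)
  W <- build_inference_matrix(fits, direction = cfg$regression$direction,
                              w_max = cfg$regression$w_max)

  # --- extraction + permutation inference ----------------------------------
  ex_cfg <- cfg$extraction
  extraction <- extract_subnetworks(W, lambda = ex_cfg$lambda,
                                    min_size = ex_cfg$min_size,
                                    max_subnetworks = ex_cfg$max_subnetworks,
                                    p_thresh = ex_cfg$p_thresh,
                                    n_restarts = ex_cfg$n_restarts)
  null <- build_null(stack, subjects, M = cfg$permutation$M,
                     seed = stage_seed(seed, "permutation"),
                     lambda = ex_cfg$lambda, min_size = ex_cfg$min_size,
                     max_subnetworks = ex_cfg$max_subnetworks,
                     p_thresh = ex_cfg$p_thresh, n_restarts = ex_cfg$n_restarts,
                     direction = cfg$regression$direction,
                     include_quadratic = if (any(fits$used_quadratic)) "always" else "never",
                     w_max = cfg$regression$w_max,
                     scheme = cfg$permutation$scheme)
  extraction <- add_pvalues(extraction, null)

  # --- mapping, hubs, mediation, cognition ---------------------------------
  subnets <- lapply(seq_along(extraction$subnetworks), function(k) {
    s <- extraction$subnetworks[[k]]
    s$rank <- k
    s$mapping <- map_to_predefined(s$nodes, parc)
    s$hubs <- as.integer(identify_hubs(W, s$nodes, p_thresh = ex_cfg$p_thresh))
    s
  })

  mediation <- cognition <- NULL
  if (isTRUE(cfg$mediation$enabled) && length(subnets) &&
      all(c("fa", "log_wmh") %in% names(subjects))) {
    cogcols <- grep("^cog[0-9]+$", names(subjects), value = TRUE)
    cogscore <- if (length(cogcols) >= 2) {
      cognitive_score(subjects[, cogcols], seed = stage_seed(seed, "cognition"))
    } else NULL
    mediation <- lapply(subnets, function(s) {
      mr <- mean_subnetwork_rsfc(stack, s$nodes)
      list(rank = s$rank,
           fa = fit_mediation(subjects$age, subjects$fa, mr, subjects$sex,
                              n_boot = cfg$mediation$n_boot,
                              seed = stage_seed(seed, "bootstrap")),
           wmh = fit_mediation(subjects$age, subjects$log_wmh, mr, subjects$sex,
                               n_boot = cfg$mediation$n_boot,
                               seed = stage_seed(seed, "bootstrap")))
    })
    if (!is.null(cogscore)) {
      cognition <- lapply(subnets, function(s) {
        mr <- mean_subnetwork_rsfc(stack, s$nodes)
        c(list(rank = s$rank), cognitive_association(cogscore, mr, subjects$age))
      })
      attr(cognition, "explained_variance") <- attr(cogscore, "explained_variance")
    }
  }

  report <- structure(list(
    n_subjects = nrow(stack$values), N = stack$N,
    parcellation_networks = sort(unique(parc$network)),
    subnetworks = subnets,
    null_summary = list(M = null$M, max_T = max(null$T_values),
                        nonzero = sum(null$T_values > 0)),
    T_values = null$T_values,
    mediation = mediation, cognition = cognition,
    truth = truth,
    config = cfg[setdiff(names(cfg), "out_dir")],
    seeds = list(master = seed,
                 cohort = stage_seed(seed, "cohort"),
                 permutation = stage_seed(seed, "permutation"),
                 bootstrap = stage_seed(seed, "bootstrap"),
                 cognition = stage_seed(seed, "cognition")),
    versions = list(r = R.version.string,
                    agenet = as.character(utils::packageVersion("agenet")))
  ), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: n = %d subjects, N = %d nodes, %d subnetwork(s)\n",
              x$n_subjects, x$N, length(x$subnetworks)))
  for (s in x$subnetworks) {
    cat(sprintf("  [%d] %d nodes, score %.2f, density %.2f, p = %.4g\n",
                s$rank, length(s$nodes), s$score, s$density, s$p_value))
  }
  invisible(x)
}

# Write the machine-readable report bundle.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report
  slim$truth <- NULL
  slim$subnetworks <- lapply(report$subnetworks, function(s) {
    s$mapping <- s$mapping[s$mapping$n_in_subnetwork > 0, ]
    s
  })
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (length(report$subnetworks)) {
    tab <- do.call(rbind, lapply(report$subnetworks, function(s) {
      data.frame(rank = s$rank, n_nodes = length(s$nodes), score = s$score,
                 density = s$density, n_edges_sig = s$n_edges_sig,
                 p_value = s$p_value,
                 nodes = paste(s$nodes, collapse = ";"),
                 hubs = paste(s$hubs, collapse = ";"))
    }))
    utils::write.csv(tab, file.path(out_dir, "subnetworks.csv"), row.names = FALSE)
  }
  writeLines(format(report$T_values, digits = 10),
             file.path(out_dir, "null_T_values.txt"))
  invisible(out_dir)
}

#' Compare two cohorts' pipeline reports
#'
#' Per-rank node-set overlap between the subnetworks of two reports from the
#' same parcellation, plus shared predefined-network tallies for the top pair.
#'
#' @param report_a,report_b `pipeline_report` objects.
#' @return List with `by_rank` (data.frame: rank, sizes, overlap count,
#'   Jaccard, hypergeometric overlap p) and `shared_networks` (networks
#'   represented in both rank-1 subnetworks).
#' @export
compare_cohorts <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "pipeline_report"), inherits(report_b, "pipeline_report"))
  if (report_a$N != report_b$N ||
      !identical(report_a$parcellation_networks, report_b$parcellation_networks)) {
    stop_invalid("reports come from different parcellations")
  }
  K <- min(length(report_a$subnetworks), length(report_b$subnetworks))
  by_rank <- do.call(rbind, lapply(seq_len(K), function(k) {
    sa <- report_a$subnetworks[[k]]$nodes
    sb <- report_b$subnetworks[[k]]$nodes
    ov <- replication_overlap(sa, sb)
    data.frame(rank = k, n_a = length(sa), n_b = length(sb),
               n_overlap = ov$n_overlap, jaccard = ov$jaccard,
               p_hypergeom = overlap_hypergeom_pvalue(sa, sb, report_a$N))
  }))
  shared <- if (K >= 1) {
    ma <- report_a$subnetworks[[1]]$mapping
    mb <- report_b$subnetworks[[1]]$mapping
    intersect(ma$network[ma$n_in_subnetwork > 0], mb$network[mb$n_in_subnetwork > 0])
  } else character(0)
  list(by_rank = by_rank, shared_networks = shared)
}
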