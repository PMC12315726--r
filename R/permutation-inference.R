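# Family-wise inference for extracted subnetworks: permute age across
# subjects (leaving connectomes and other covariates attached), re-run the
# edge regression and extraction, and record the maximum subnetwork score per
# permutation. Every observed subnetwork is compared against this single
# max-statistic null, which controls the family-wise error rate.

#' Build the max-statistic permutation null
#'
#' For each of `M` permutations the subjects' ages are shuffled (the quadratic
#' age term, when used, is recomputed from the permuted ages), the edge-wise
#' regression is refit, the inference matrix is rebuilt with the same
#' direction mask, subnetworks are re-extracted with the same configuration,
#' and `T_k` is the maximum subnetwork score (0 when nothing is extracted).
#'
#' @param stack Imputed [connectome_stack()].
#' @param subjects Aligned `subject_table`.
#' @param M Number of permutations (>= 1).
#' @param seed Integer seed driving the permutation stream.
#' @param lambda,min_size,max_subnetworks,p_thresh,n_restarts Extraction
#'   configuration; must match the observed-data run.
#' @param direction Direction mask of the inference matrix (default
#'   `"negative"`).
#' @param include_quadratic Quadratic-term handling, as in [fit_edges()].
#' @param w_max Cap on `-log10(p)`.
#' @param scheme `"draper_stoneman"` (permute the age column; default) or
#'   `"freedman_lane"` (permute reduced-model residuals).
#' @param confound_cols Confound column names (defaults as in [fit_edges()]).
#' @return A `permutation_null`: list with `T_values` (length `M`), `M`,
#'   `seed`, `scheme`, and the extraction config.
#' @export
build_null <- function(stack, subjects, M = 1000L, seed = NULL,
                       lambda = default_lambda(), min_size = 5L,
                       max_subnetworks = 10L, p_thresh = 0.05, n_restarts = 5L,
                       direction = "negative",
                       include_quadratic = c("never", "always"),
                       w_max = 50,
                       scheme = c("draper_stoneman", "freedman_lane"),
                       confound_cols = NULL) {
  include_quadratic <- match.arg(include_quadratic)
  scheme <- match.arg(scheme)
  stopifnot(inherits(stack, "connectome_stack"))
  check_alignment(stack, subjects)
  if (!is.numeric(M) || M < 1) stop_invalid("M must be >= 1")
  if (any(stack$missing)) stop_invalid("stack has missing entries; run impute_missing() first")
  M <- as.integer(M)
  Y <- stack$values
  n <- nrow(Y)
  quad <- include_quadratic == "always"
  confound_cols <- confound_cols %||% intersect(paste0("conf", 1:5), names(subjects))

  if (scheme == "freedman_lane") {
    # reduced model: everything but age; permute its residuals
    Z <- build_design(subjects, quadratic = FALSE, confound_cols = confound_cols)
    Z <- Z[, setdiff(colnames(Z), c("age", "age_sq")), drop = FALSE]
    ZtZinv <- chol2inv(chol(crossprod(Z)))
    Bz <- ZtZinv %*% crossprod(Z, Y)
    fitted0 <- Z %*% Bz
    resid0 <- Y - fitted0
    X_obs <- build_design(subjects, quadratic = quad, confound_cols = confound_cols)
  }

  T_values <- with_seed(seed, vapply(seq_len(M), function(k) {
    perm <- sample.int(n)
    if (scheme == "draper_stoneman") {
      Xp <- build_design(subjects, quadratic = quad,
                         confound_cols = confound_cols,
                         age = subjects$age[perm])
      fit <- ols_fit_matrix(Y, Xp, age_col = 2L)
    } else {
      Yp <- fitted0 + resid0[perm, , drop = FALSE]
      fit <- ols_fit_matrix(Yp, X_obs, age_col = 2L)
    }
    Wp <- inference_matrix_from_p(fit$p_age, sign(fit$t_age), stack$N,
                                  direction, w_max, warn_underflow = FALSE)
    ex <- extract_subnetworks(Wp, lambda = lambda, min_size = min_size,
                              max_subnetworks = max_subnetworks,
                              p_thresh = p_thresh, n_restarts = n_restarts)
    if (length(ex$subnetworks)) ex$subnetworks[[1]]$score else 0
  }, numeric(1)))

  structure(list(T_values = T_values, M = M, seed = seed, scheme = scheme,
                 config = list(lambda = lambda, min_size = min_size,
                               max_subnetworks = max_subnetworks,
                               direction = direction, p_thresh = p_thresh,
                               n_restarts = n_restarts,
                               include_quadratic = include_quadratic)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: M = %d (%s scheme), %d nonzero maxima, max T = %.3f\n",
              x$M, x$scheme, sum(x$T_values > 0), max(x$T_values)))
  invisible(x)
}

#' Permutation p-value of an observed subnetwork score
#'
#' Add-one percentile rank of `T_obs` within the null maxima:
#' `p = (1 + #\{T_k >= T_obs\}) / (M + 1)`, so the smallest attainable value
#' at M permutations is `1/(M+1)`.
#'
#' @param T_obs Observed subnetwork score (finite).
#' @param null A `permutation_null` from [build_null()].
#' @return p-value in (0, 1].
#' @export
subnetwork_pvalue <- function(T_obs, null) {
  stopifnot(inherits(null, "permutation_null"))
  if (!is.numeric(T_obs) || !is.finite(T_obs)) stop_invalid("T_obs must be finite")
  (1 + sum(null$T_values >= T_obs)) / (null$M + 1)
}

#' Attach permutation p-values to an extraction result
#'
#' Every extracted subnetwork is tested against the single max-statistic null
#' (family-wise control).
#'
#' @param extraction An `extraction_result`.
#' @param null A `permutation_null`.
#' @return The extraction result with a `p_value` on each subnetwork.
#' @export
add_pvalues <- function(extraction, null) {
  stopifnot(inherits(extraction, "extraction_result"))
  extraction$subnetworks <- lapply(extraction$subnetworks, function(s) {
    s$p_value <- subnetwork_pvalue(s$score, null)
    s
  })
  extraction
}
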