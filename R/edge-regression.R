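# Mass-univariate edge regression. All N(N-1)/2 edges share one design
# matrix, so the cohort is fit in a handful of matrix products (one QR of the
# design, reused across edges) instead of an lm() per edge.

# Core vectorized OLS over an n x E response matrix.
# Returns coefficients, the age-column t/p, and per-edge RSS.
ols_fit_matrix <- function(Y, X, age_col) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || qr(X)$rank < p) {
    cors <- abs(stats::cor(X[, -1, drop = FALSE]))
    diag(cors) <- 0
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    nm <- colnames(X)[-1][worst]
    stop(structure(class = c("agenet_design_error", "error", "condition"),
                   list(message = paste0("design matrix is rank deficient (collinear columns: ",
                                         paste(nm, collapse = ", "), ")"),
                        call = sys.call())))
  }
  XtXinv <- chol2inv(R)
  B <- XtXinv %*% crossprod(X, Y)           # p x E
  res <- Y - X %*% B
  rss <- colSums(res^2)
  df <- n - p
  sigma2 <- rss / df
  se_age <- sqrt(sigma2 * XtXinv[age_col, age_col])
  t_age <- B[age_col, ] / se_age
  degenerate <- sigma2 <= 1e-24 * pmax(colMeans(Y^2), 1e-300)
  if (any(degenerate)) {
    t_age[degenerate] <- 0
    warning(sum(degenerate), " edge(s) with zero residual variance: t set to 0, p to 1")
  }
  p_age <- 2 * stats::pt(-abs(t_age), df)
  p_age[degenerate] <- 1
  list(beta = B, t_age = t_age, p_age = p_age, rss = rss, df = df,
       XtXinv = XtXinv)
}

# Build the shared design matrix from a subject table. Age is centered (the
# slope and its t are unchanged; with a quadratic term the age coefficient is
# then the slope at the mean age). The quadratic term is centered age squared.
build_design <- function(subjects, quadratic = FALSE, confound_cols = NULL, age = NULL) {
  age <- age %||% subjects$age
  age_c <- age - mean(age)
  confound_cols <- confound_cols %||%
    intersect(paste0("conf", 1:5), names(subjects))
  X <- cbind(`(Intercept)` = 1, age = age_c)
  if (quadratic) X <- cbind(X, age_sq = age_c^2)
  X <- cbind(X, sex = subjects$sex)
  if (length(confound_cols)) {
    X <- cbind(X, as.matrix(subjects[, confound_cols, drop = FALSE]))
  }
  X
}

#' Edge-wise regression of connectivity on age
#'
#' Fits, for every edge, an ordinary least-squares model of the Fisher-z edge
#' value on age (optionally age-squared), sex, and the imaging confounds, with
#' an identity link. The fit is vectorized across edges (shared design, one
#' factorization) and agrees with per-edge reference fits to numerical
#' precision. The age t-statistic and two-sided p-value per edge are the
#' inputs of the inference matrix.
#'
#' @param stack An imputed [connectome_stack()] (no missing entries).
#' @param subjects Aligned `subject_table` with `age`, `sex`, and confound
#'   columns.
#' @param include_quadratic `"auto"` (apply [quadratic_rule()]), `"never"`, or
#'   `"always"`.
#' @param alpha,r2_min Parameters of the quadratic-term rule: the term is kept
#'   only when significant with partial r-squared at least `r2_min`
#'   (default 1%).
#' @param quad_scope `"global"` (one decision for all edges, the default) or
#'   `"per_edge"`.
#' @param confound_cols Names of confound columns; defaults to whichever of
#'   `conf1..conf5` are present.
#' @return A data.frame of class `edge_fits`: columns `i`, `j` (0-based node
#'   ids), the fitted coefficients, `t_age`, `p_age`, `partial_r2_agesq`,
#'   `used_quadratic`. Node count, df and design metadata are attached as
#'   attributes.
#' @export
fit_edges <- function(stack, subjects,
                      include_quadratic = c("auto", "never", "always"),
                      alpha = 0.05, r2_min = 0.01,
                      quad_scope = c("global", "per_edge"),
                      confound_cols = NULL) {
  include_quadratic <- match.arg(include_quadratic)
  quad_scope <- match.arg(quad_scope)
  stopifnot(inherits(stack, "connectome_stack"))
  check_alignment(stack, subjects)
  if (any(stack$missing)) stop_invalid("stack has missing entries; run impute_missing() first")
  Y <- stack$values
  confound_cols <- confound_cols %||% intersect(paste0("conf", 1:5), names(subjects))

  X0 <- build_design(subjects, quadratic = FALSE, confound_cols = confound_cols)
  fit0 <- ols_fit_matrix(Y, X0, age_col = 2L)
  partial_r2 <- rep(NA_real_, ncol(Y))
  used <- rep(FALSE, ncol(Y))
  fit1 <- NULL
  if (include_quadratic != "never") {
    X1 <- build_design(subjects, quadratic = TRUE, confound_cols = confound_cols)
    fit1 <- ols_fit_matrix(Y, X1, age_col = 2L)
    partial_r2 <- pmax(0, (fit0$rss - fit1$rss) / fit0$rss)
    se_q <- sqrt(fit1$rss / fit1$df * fit1$XtXinv[3, 3])
    t_q <- ifelse(se_q > 0, fit1$beta[3, ] / se_q, 0)
    p_quad <- 2 * stats::pt(-abs(t_q), fit1$df)
    used <- if (include_quadratic == "always") rep(TRUE, ncol(Y)) else
      quadratic_rule(p_quad, partial_r2, alpha = alpha, r2_min = r2_min,
                     scope = quad_scope)
    used <- rep_len(used, ncol(Y))
  }

  idx <- edge_index(stack$N)
  if (is.null(fit1)) {
    betas <- data.frame(beta0 = fit0$beta[1, ], beta_age = fit0$beta[2, ],
                        beta_age_sq = NA_real_)
    t_age <- fit0$t_age; p_age <- fit0$p_age
  } else {
    betas <- data.frame(
      beta0 = ifelse(used, fit1$beta[1, ], fit0$beta[1, ]),
      beta_age = ifelse(used, fit1$beta[2, ], fit0$beta[2, ]),
      beta_age_sq = ifelse(used, fit1$beta[3, ], NA_real_))
    t_age <- ifelse(used, fit1$t_age, fit0$t_age)
    p_age <- ifelse(used, fit1$p_age, fit0$p_age)
  }
  out <- data.frame(idx, betas, t_age = t_age, p_age = p_age,
                    partial_r2_agesq = partial_r2,
                    used_quadratic = used)
  structure(out, class = c("edge_fits", "data.frame"),
            N = stack$N, n_subjects = nrow(Y), df = fit0$df,
            confound_cols = confound_cols, rss = fit0$rss,
            rss_quadratic = if (!is.null(fit1)) fit1$rss else NULL)
}

#' Decision rule for the quadratic age term
#'
#' The quadratic term is retained only if it is statistically significant and
#' carries a non-trivial effect size (partial r-squared of at least `r2_min`,
#' default 1%). With `scope = "global"` one decision is made for the whole
#' connectome from the median p-value and median partial r-squared across
#' edges; `"per_edge"` returns one decision per edge.
#'
#' @param p_quad Per-edge p-values of the quadratic coefficient.
#' @param partial_r2 Per-edge partial r-squared of the quadratic term.
#' @param alpha Significance level (default 0.05).
#' @param r2_min Minimum partial r-squared (default 0.01).
#' @param scope `"global"` or `"per_edge"`.
#' @return A single logical (global) or one per edge.
#' @export
quadratic_rule <- function(p_quad, partial_r2, alpha = 0.05, r2_min = 0.01,
                           scope = c("global", "per_edge")) {
  scope <- match.arg(scope)
  if (scope == "global") {
    stats::median(p_quad) < alpha && stats::median(partial_r2) >= r2_min
  } else {
    p_quad < alpha & partial_r2 >= r2_min
  }
}

#' Build the -log10(p) inference matrix from edge fits
#'
#' Entry (i, j) is `-log10(p_ij)` of the age effect on that edge. With
#' `direction = "negative"` (the default, targeting age-related connectivity
#' decreases) entries whose age coefficient is non-negative are zeroed;
#' symmetrically for `"positive"`; `"both"` keeps all. The sign matrix of the
#' age coefficients is always retained.
#'
#' @param fits An `edge_fits` table from [fit_edges()].
#' @param direction `"negative"`, `"positive"`, or `"both"`.
#' @param w_max Cap on `-log10(p)` for p-value underflow (default 50).
#' @return An `inference_matrix`: list with symmetric `W` (nonnegative,
#'   zero diagonal), `sign` in {-1, 0, 1}, `N`, and the direction used.
#' @export
build_inference_matrix <- function(fits, direction = c("negative", "positive", "both"),
                                   w_max = 50) {
  direction <- match.arg(direction)
  N <- attr(fits, "N")
  inference_matrix_from_p(fits$p_age, sign(fits$t_age), N, direction, w_max)
}

# Shared by build_inference_matrix() and the permutation loop.
inference_matrix_from_p <- function(p, sgn, N, direction, w_max = 50,
                                    warn_underflow = TRUE) {
  w <- -log10(p)
  over <- !is.finite(w) | w > w_max
  if (any(over)) {
    if (warn_underflow) warning(sum(over), " p-value(s) underflowed; w capped at ", w_max)
    w[over] <- w_max
  }
  if (direction == "negative") w[sgn >= 0] <- 0
  if (direction == "positive") w[sgn <= 0] <- 0
  structure(list(W = edges_to_matrix(w, N), sign = edges_to_matrix(sgn, N),
                 N = N, direction = direction, w_max = w_max),
            class = "inference_matrix")
}

#' @export
print.inference_matrix <- function(x, ...) {
  cat(sprintf("inference_matrix: %d x %d, direction = %s, %d nonzero entries, max w = %.2f\n",
              x$N, x$N, x$direction, sum(x$W > 0) / 2, max(x$W)))
  invisible(x)
}

# Accept an inference_matrix or a plain symmetric matrix.
as_w_matrix <- function(x) {
  if (inherits(x, "inference_matrix")) return(x$W)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || any(x < 0, na.rm = TRUE)) {
    stop_invalid("expected an inference_matrix or a nonnegative symmetric matrix")
  }
  diag(x) <- 0
  x
}
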