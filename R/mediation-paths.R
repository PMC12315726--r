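# Linear path (mediation) analysis: age -> mediator -> mean subnetwork
# connectivity, sex-adjusted. For a just-identified linear path model the
# structural-equation fit is exactly two nested OLS regressions, so the model
# is estimated that way; uncertainty for the indirect effect and the
# proportion mediated comes from a nonparametric subject bootstrap, with a
# delta-method interval reported alongside.

#' Per-subject mean connectivity of a subnetwork
#'
#' @param stack Imputed [connectome_stack()].
#' @param S Integer vector of 0-based node ids (at least 2).
#' @return Numeric vector, one value per subject: the mean of the
#'   `|S|(|S|-1)/2` intra-S edge values.
#' @export
mean_subnetwork_rsfc <- function(stack, S) {
  stopifnot(inherits(stack, "connectome_stack"))
  S <- unique(as.integer(S))
  if (length(S) < 2L) stop_invalid("S needs at least 2 nodes")
  if (any(S < 0 | S >= stack$N)) stop_invalid("S contains unknown nodes")
  if (any(stack$missing)) stop_invalid("stack has missing entries; run impute_missing() first")
  e <- intra_edges(S, stack$N)
  rowMeans(stack$values[, e, drop = FALSE])
}

# One pass of the two-regression path fit on prepared design columns.
# `sex` may be NULL (no adjustment).
path_coefs <- function(age, mediator, outcome, sex) {
  Xm <- cbind(1, age, sex)
  Xy <- cbind(1, age, mediator, sex)
  cm <- .lm.fit(Xm, mediator)$coefficients
  cy <- .lm.fit(Xy, outcome)$coefficients
  c(a = cm[2], b = cy[3], c_prime = cy[2])
}

#' Fit a single-mediator linear path model
#'
#' `a` from `mediator ~ age + sex`; `b` and `c_prime` from
#' `outcome ~ age + mediator + sex`. The indirect effect is `a*b`, the total
#' effect `a*b + c_prime` (exactly the age coefficient of the reduced model
#' `outcome ~ age + sex`), and the proportion mediated their ratio.
#'
#' @param age,mediator,outcome Aligned numeric vectors (n >= 10).
#' @param sex Optional aligned 0/1 adjustment covariate.
#' @param n_boot Bootstrap resamples (>= 100) for the percentile CI and the
#'   indirect-effect p-value.
#' @param seed Seed for the bootstrap stream.
#' @param ci_level Confidence level (default 0.95).
#' @param total_tol If `|total| < total_tol * sd(outcome)/sd(age)` the
#'   proportion mediated is flagged unstable (near-zero denominator).
#' @return A `mediation_result`: `a`, `b`, `c_prime`, `indirect`, `total`,
#'   `prop_mediated`, bootstrap percentile `ci` (and `ci_indirect`),
#'   delta-method `ci_delta` for the indirect effect, `p_indirect`, `n`,
#'   `n_boot`, `seed`, `unstable`.
#' @export
fit_mediation <- function(age, mediator, outcome, sex = NULL,
                          n_boot = 1000L, seed = NULL, ci_level = 0.95,
                          total_tol = 1e-6) {
  n <- length(age)
  if (n < 10L || length(mediator) != n || length(outcome) != n) {
    stop_invalid("age, mediator, outcome must be aligned with n >= 10")
  }
  if (n_boot < 100L) stop_invalid("n_boot must be >= 100")
  if (!is.null(sex) && stats::sd(sex) == 0) sex <- NULL
  ok <- if (is.null(sex)) stats::complete.cases(age, mediator, outcome) else
    stats::complete.cases(age, mediator, outcome, sex)
  age <- age[ok]; mediator <- mediator[ok]; outcome <- outcome[ok]
  if (!is.null(sex)) sex <- sex[ok]
  n <- length(age)
  if (stats::sd(age) == 0 || stats::sd(mediator) == 0 || stats::sd(outcome) == 0) {
    stop(structure(class = c("agenet_degenerate_input", "error", "condition"),
                   list(message = "zero variance in age, mediator, or outcome",
                        call = sys.call())))
  }

  est <- path_coefs(age, mediator, outcome, sex)
  indirect <- est[["a"]] * est[["b"]]
  total <- indirect + est[["c_prime"]]
  prop <- indirect / total
  unstable <- abs(total) < total_tol * stats::sd(outcome) / stats::sd(age)
  if (unstable) warning("total effect near zero; proportion mediated is unstable")

  # delta-method SE for the indirect effect (independent a, b to first order)
  se_ab <- function(x, y, X) {
    f <- stats::lm.fit(X, y)
    s2 <- sum(f$residuals^2) / (length(y) - ncol(X))
    sqrt(s2 * chol2inv(chol(crossprod(X)))[x, x])
  }
  se_a <- se_ab(2, mediator, cbind(1, age, sex))
  se_b <- se_ab(3, outcome, cbind(1, age, mediator, sex))
  se_ind <- sqrt(est[["b"]]^2 * se_a^2 + est[["a"]]^2 * se_b^2)
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci_delta <- indirect + c(-1, 1) * zq * se_ind

  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      cb <- path_coefs(age[idx], mediator[idx], outcome[idx], sex[idx])
      if (anyNA(cb)) cb <- path_coefs(age[idx], mediator[idx], outcome[idx], NULL)
      ind <- cb[["a"]] * cb[["b"]]
      c(ind, ind / (ind + cb[["c_prime"]]))
    }, numeric(2))
  })
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  ci_ind <- stats::quantile(boot[1, ], probs, names = FALSE)
  ci_prop <- stats::quantile(boot[2, ], probs, names = FALSE)
  p_ind <- min(1, 2 * (1 + min(sum(boot[1, ] <= 0), sum(boot[1, ] >= 0))) / (n_boot + 1))

  structure(list(a = est[["a"]], b = est[["b"]], c_prime = est[["c_prime"]],
                 indirect = indirect, total = total, prop_mediated = prop,
                 ci = ci_prop, ci_indirect = ci_ind, ci_delta = ci_delta,
                 p_indirect = p_ind, ci_level = ci_level, n = n,
                 n_boot = as.integer(n_boot), seed = seed, unstable = unstable),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation: a = %.4f, b = %.4f, c' = %.4f\n", x$a, x$b, x$c_prime))
  cat(sprintf("  indirect = %.4f, total = %.4f\n", x$indirect, x$total))
  cat(sprintf("  proportion mediated = %.1f%% (%.0f%% bootstrap CI [%.1f%% %.1f%%]), p_indirect = %.4g\n",
              100 * x$prop_mediated, 100 * x$ci_level, 100 * x$ci[1], 100 * x$ci[2],
              x$p_indirect))
  if (x$unstable) cat("  WARNING: total effect near zero; proportion unstable\n")
  invisible(x)
}

#' General cognitive score from a nine-assessment battery
#'
#' Missing entries are imputed by predictive mean matching (linear predictor
#' on the other assessments, `k` nearest donors, one seeded draw), the battery
#' is standardized, and the score is its first principal component, oriented
#' so that higher = better (positive mean loading) and scaled to unit
#' variance. The PC1 explained-variance fraction is attached as attribute
#' `"explained_variance"`.
#'
#' @param battery Numeric matrix or data.frame, subjects x assessments (>= 2
#'   columns with data).
#' @param k PMM donor-pool size (default 5).
#' @param seed Seed for the donor draws.
#' @return Numeric score per subject (`NA` when every assessment is missing),
#'   with attributes `explained_variance` and `loadings`.
#' @export
cognitive_score <- function(battery, k = 5L, seed = NULL) {
  B <- as.matrix(battery)
  all_na <- colSums(!is.na(B)) == 0
  if (any(all_na)) {
    warning("dropping all-missing assessment column(s): ",
            paste(colnames(B)[all_na] %||% which(all_na), collapse = ", "))
    B <- B[, !all_na, drop = FALSE]
  }
  if (ncol(B) < 2L) stop_invalid("need at least 2 assessment columns with data")
  subj_all_na <- rowSums(!is.na(B)) == 0

  if (anyNA(B[!subj_all_na, ])) B <- pmm_impute(B, k = k, seed = seed)
  Bs <- scale(B[!subj_all_na, , drop = FALSE])
  pc <- stats::prcomp(Bs, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, 1]
  if (mean(load) < 0) load <- -load
  score_core <- as.vector(Bs %*% load)
  score_core <- score_core / stats::sd(score_core)
  score <- rep(NA_real_, nrow(B))
  score[!subj_all_na] <- score_core
  structure(score,
            explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2),
            loadings = load)
}

# Predictive mean matching, single seeded draw. Columns with missing values
# are imputed from a linear predictor on the other (mean-filled) columns;
# each missing cell takes the observed value of one of its k nearest donors
# by predicted mean.
pmm_impute <- function(B, k = 5L, seed = NULL) {
  with_seed(seed, {
    filled <- apply(B, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE); col
    })
    out <- B
    for (j in seq_len(ncol(B))) {
      miss <- is.na(B[, j])
      if (!any(miss)) next
      obs <- !miss
      X <- cbind(1, filled[, -j, drop = FALSE])
      beta <- stats::lm.fit(X[obs, , drop = FALSE], B[obs, j])$coefficients
      beta[is.na(beta)] <- 0
      pred <- as.vector(X %*% beta)
      donors_pool <- which(obs)
      for (i in which(miss)) {
        d <- donors_pool[order(abs(pred[donors_pool] - pred[i]))[seq_len(min(k, length(donors_pool)))]]
        out[i, j] <- B[sample(rep(d, 2), 1), j]
      }
    }
    out
  })
}

#' Association between subnetwork connectivity and cognition
#'
#' OLS of the cognitive score on mean subnetwork connectivity, controlling
#' for age: `score ~ mean_rsfc + age`.
#'
#' @param score Per-subject cognitive score.
#' @param mean_rsfc Per-subject mean subnetwork connectivity.
#' @param age Per-subject age.
#' @param ci_level Confidence level (default 0.95).
#' @return List with `coefficient` (cognitive-score units per unit rsFC),
#'   `se`, `ci`, `p_value`, `n`.
#' @export
cognitive_association <- function(score, mean_rsfc, age, ci_level = 0.95) {
  ok <- stats::complete.cases(score, mean_rsfc, age)
  df <- data.frame(score = score[ok], rsfc = mean_rsfc[ok], age = age[ok])
  if (stats::sd(df$rsfc) == 0 ||
      suppressWarnings(summary(stats::lm(rsfc ~ age, df))$r.squared) > 1 - 1e-10) {
    stop(structure(class = c("agenet_design_error", "error", "condition"),
                   list(message = "rsFC is collinear with age; association not identifiable",
                        call = sys.call())))
  }
  fit <- stats::lm(score ~ rsfc + age, df)
  sm <- summary(fit)$coefficients
  est <- sm["rsfc", "Estimate"]; se <- sm["rsfc", "Std. Error"]
  tq <- stats::qt(1 - (1 - ci_level) / 2, fit$df.residual)
  list(coefficient = est, se = se, ci = est + c(-1, 1) * tq * se,
       p_value = sm["rsfc", "Pr(>|t|)"], n = nrow(df))
}
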