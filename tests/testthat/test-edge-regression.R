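test_that("vectorized fits match per-edge lm reference fits", {
  coh <- make_null_cohort(n = 80, N = 12, seed = 2)
  fits <- fit_edges(coh$stack, coh$subjects, include_quadratic = "never")
  subj <- coh$subjects
  age_c <- subj$age - mean(subj$age)
  set.seed(99)
  for (e in sample(nrow(fits), 20)) {
    y <- coh$stack$values[, e]
    ref <- lm(y ~ age_c + sex + conf1 + conf2 + conf3 + conf4 + conf5, data = subj)
    sm <- summary(ref)$coefficients
    expect_equal(fits$beta_age[e], sm["age_c", "Estimate"], tolerance = 1e-8)
    expect_equal(fits$t_age[e], sm["age_c", "t value"], tolerance = 1e-8)
    expect_equal(fits$p_age[e], sm["age_c", "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("degenerate and rank-deficient designs follow the error contract", {
  coh <- make_null_cohort(n = 40, N = 6, seed = 3)
  coh$stack$values[, 2] <- 1.5               # constant edge across subjects
  expect_warning(fits <- fit_edges(coh$stack, coh$subjects, include_quadratic = "never"),
                 "zero residual variance")
  expect_identical(fits$t_age[2], 0)
  expect_identical(fits$p_age[2], 1)

  subj <- coh$subjects
  subj$conf2 <- subj$conf1                   # collinear confounds
  err <- tryCatch(fit_edges(coh$stack, subj, include_quadratic = "never"),
                  error = identity)
  expect_s3_class(err, "agenet_design_error")
  expect_match(conditionMessage(err), "conf")

  miss <- coh$stack; miss$values[1, 1] <- NA; miss$missing[1, 1] <- TRUE
  expect_error(fit_edges(miss, coh$subjects), class = "agenet_invalid_argument")
})

test_that("the quadratic-age rule fires only on real curvature of non-trivial size", {
  lin <- generate_cohort(cohort_spec(n_subjects = 400, n_nodes = 12,
                                     planted = list(planted_subnetwork(0:5, beta_age = -0.005))),
                         seed = 8)
  fits_lin <- fit_edges(lin$stack, lin$subjects, include_quadratic = "auto")
  expect_false(any(fits_lin$used_quadratic))

  # strong curvature on every edge: partial r2 well above 1%
  quad <- generate_cohort(cohort_spec(n_subjects = 400, n_nodes = 12, planted = list(
    planted_subnetwork(0:11, beta_age = 0, beta_age_sq = 4e-4)),
    noise_sd = 0.2), seed = 9)
  fits_q <- fit_edges(quad$stack, quad$subjects, include_quadratic = "auto")
  expect_true(all(fits_q$used_quadratic))
  expect_gt(median(fits_q$partial_r2_agesq), 0.01)

  # unreachable effect-size floor always says no
  fits_q2 <- fit_edges(quad$stack, quad$subjects, include_quadratic = "auto", r2_min = 1)
  expect_false(any(fits_q2$used_quadratic))

  # rule exposed directly
  expect_true(quadratic_rule(rep(1e-6, 10), rep(0.05, 10)))
  expect_false(quadratic_rule(rep(0.5, 10), rep(0.001, 10)))
  expect_identical(quadratic_rule(c(1e-6, 0.9), c(0.05, 0.05), scope = "per_edge"),
                   c(TRUE, FALSE))
})

test_that("inference matrix transforms, masks, and caps p-values", {
  N <- 3
  fits <- make_fits(p = c(0.05, 1, 1e-60), sgn = c(-1, -1, -1), N = N)
  expect_warning(W <- build_inference_matrix(fits, direction = "both"), "underflow")
  expect_equal(W$W[1, 2], -log10(0.05), tolerance = 1e-6)
  expect_identical(W$W[1, 3], 0)
  expect_identical(W$W[2, 3], 50)        # capped underflow
  expect_identical(diag(W$W), rep(0, N))
  expect_equal(W$W, t(W$W))
  expect_warning(build_inference_matrix(make_fits(0, -1, 2)), "underflow")

  # direction masks zero the opposing sign but keep the sign matrix
  fits2 <- make_fits(p = c(0.01, 0.01, 0.01), sgn = c(-1, 1, -1), N = N)
  Wneg <- build_inference_matrix(fits2, direction = "negative")
  expect_identical(Wneg$W[1, 3], 0)
  expect_identical(Wneg$sign[1, 3], 1)
  expect_gt(Wneg$W[1, 2], 0)
  Wpos <- build_inference_matrix(fits2, direction = "positive")
  expect_gt(Wpos$W[1, 3], 0)
  expect_identical(Wpos$W[1, 2], 0)

  # under the null about half the entries carry each sign
  coh <- make_null_cohort(n = 120, N = 25, seed = 13)
  fits3 <- fit_edges(coh$stack, coh$subjects, include_quadratic = "never")
  frac_neg <- mean(fits3$t_age < 0)
  expect_gt(frac_neg, 0.4); expect_lt(frac_neg, 0.6)
})

test_that("the inference matrix is invariant to joint subject reordering", {
  coh <- make_null_cohort(n = 60, N = 10, seed = 17)
  fits <- fit_edges(coh$stack, coh$subjects, include_quadratic = "never")
  perm <- sample(60)
  stack2 <- connectome_stack(coh$stack$values[perm, ], coh$stack$N,
                             coh$stack$subject_ids[perm])
  subj2 <- as_subject_table(coh$subjects[perm, ])
  fits2 <- fit_edges(stack2, subj2, include_quadratic = "never")
  expect_equal(build_inference_matrix(fits2)$W, build_inference_matrix(fits)$W,
               tolerance = 1e-10)
})
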