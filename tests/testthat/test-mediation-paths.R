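test_that("mean subnetwork connectivity averages the intra-set edges", {
  coh <- make_null_cohort(n = 20, N = 8, seed = 51)
  stack <- coh$stack
  e <- pair_to_edge(2, 5, 8)
  expect_equal(mean_subnetwork_rsfc(stack, c(2, 5)), stack$values[, e])

  const <- connectome_stack(matrix(0.7, 4, edge_count(6)), 6)
  expect_equal(mean_subnetwork_rsfc(const, 0:5), rep(0.7, 4))

  # planted cohort: mean subnetwork rsFC declines with age
  pl <- generate_cohort(cohort_spec(n_subjects = 400, n_nodes = 20,
                                    planted = list(planted_subnetwork(0:9, beta_age = -0.005))),
                        seed = 52)
  mr <- mean_subnetwork_rsfc(impute_missing(pl$stack), 0:9)
  expect_lt(coef(lm(mr ~ pl$subjects$age))[2], 0)

  expect_error(mean_subnetwork_rsfc(stack, 3), class = "agenet_invalid_argument")
})

test_that("path fits recover planted coefficients and obey the linear identity", {
  dat <- simulate_mediation(5000, a = -0.5, b = 0.4, c_prime = -0.8,
                            sd_mediator = 0.3, sd_outcome = 0.3, seed = 1)
  fit <- fit_mediation(dat$exposure, dat$mediator, dat$outcome, dat$sex,
                       n_boot = 300, seed = 2)
  expect_equal(fit$a, -0.5, tolerance = 0.03)
  expect_equal(fit$b, 0.4, tolerance = 0.03)
  expect_equal(fit$prop_mediated, 0.2, tolerance = 0.02)
  expect_true(fit$ci[1] <= fit$prop_mediated && fit$prop_mediated <= fit$ci[2])

  # total = c' + a*b equals the reduced-model age coefficient exactly
  for (s in 1:5) {
    d <- simulate_mediation(200, a = rnorm(1), b = rnorm(1), c_prime = rnorm(1),
                            seed = 10 + s)
    f <- fit_mediation(d$exposure, d$mediator, d$outcome, d$sex,
                       n_boot = 100, seed = 1)
    reduced <- coef(lm(outcome ~ exposure + sex, data = d))[["exposure"]]
    expect_equal(f$total, reduced, tolerance = 1e-10)
  }
})

test_that("null indirect paths give CIs covering zero; seeds fix the bootstrap", {
  dat <- simulate_mediation(800, a = 0, b = 0.4, c_prime = -0.5, seed = 3)
  fit <- fit_mediation(dat$exposure, dat$mediator, dat$outcome,
                       n_boot = 300, seed = 4)
  expect_lt(abs(fit$indirect), 0.05)
  expect_true(fit$ci_indirect[1] <= 0 && 0 <= fit$ci_indirect[2])
  expect_gt(fit$p_indirect, 0.05)

  fit2 <- fit_mediation(dat$exposure, dat$mediator, dat$outcome,
                        n_boot = 300, seed = 4)
  expect_identical(fit$ci, fit2$ci)
  expect_identical(fit$ci_indirect, fit2$ci_indirect)
})

test_that("proportion mediated is scale invariant and degenerate inputs error", {
  dat <- simulate_mediation(500, seed = 5)
  f0 <- fit_mediation(dat$exposure, dat$mediator, dat$outcome, n_boot = 100, seed = 1)
  f1 <- fit_mediation(dat$exposure, 10 * dat$mediator, dat$outcome, n_boot = 100, seed = 1)
  f2 <- fit_mediation(dat$exposure, dat$mediator, 0.1 * dat$outcome, n_boot = 100, seed = 1)
  expect_equal(f1$prop_mediated, f0$prop_mediated, tolerance = 1e-10)
  expect_equal(f2$prop_mediated, f0$prop_mediated, tolerance = 1e-10)

  expect_error(fit_mediation(dat$exposure, rep(1, 500), dat$outcome, n_boot = 100),
               class = "agenet_degenerate_input")
  expect_error(fit_mediation(1:5, 1:5, 1:5), class = "agenet_invalid_argument")

  # near-cancelling direct and indirect effects flag instability
  d2 <- simulate_mediation(2000, a = 0.5, b = 0.4, c_prime = -0.2,
                           sd_mediator = 1e-4, sd_outcome = 1e-4, seed = 6)
  expect_warning(fit_mediation(d2$exposure, d2$mediator, d2$outcome,
                               n_boot = 100, seed = 1, total_tol = 10),
                 "unstable")
})

test_that("cognitive scores are PC1 of the standardized battery with PMM for gaps", {
  set.seed(60)
  one <- rnorm(100)
  ident <- matrix(one, 100, 9)
  s <- cognitive_score(ident)
  expect_equal(attr(s, "explained_variance"), 1)
  expect_equal(abs(cor(s, one)), 1, tolerance = 1e-10)

  # complete data: imputation is a no-op, score equals direct PC1
  B <- sapply(1:9, function(j) 0.8 * one + rnorm(100, 0, 0.6))
  s2 <- cognitive_score(B, seed = 1)
  pc <- prcomp(scale(B))
  ref <- pc$x[, 1] / sd(pc$x[, 1])
  expect_equal(abs(cor(s2, ref)), 1, tolerance = 1e-10)
  expect_gt(cor(s2, one), 0)                      # oriented: higher = better

  # missing entries: PMM fills from observed donor values
  Bm <- B; Bm[sample(900, 45)] <- NA
  s3 <- cognitive_score(Bm, seed = 2)
  expect_false(anyNA(s3))
  expect_gt(cor(s3, s2), 0.95)
  expect_identical(cognitive_score(Bm, seed = 2), s3)  # seeded determinism

  # all-missing column dropped with warning; all-missing subject -> NA score
  Bc <- B; Bc[, 4] <- NA; Bc[7, ] <- NA
  expect_warning(s4 <- cognitive_score(Bc, seed = 3), "all-missing")
  expect_true(is.na(s4[7]))
  expect_false(anyNA(s4[-7]))
})

test_that("cognition-connectivity association recovers a planted coefficient", {
  set.seed(70)
  n <- 1000
  age <- runif(n, 44, 82)
  rsfc <- 0.5 - 0.004 * age + rnorm(n, 0, 0.05)
  score <- 0.4 * rsfc + rnorm(n, 0, 0.02)
  fit <- cognitive_association(score, rsfc, age)
  expect_equal(fit$coefficient, 0.4, tolerance = 0.05)
  expect_true(fit$ci[1] <= 0.4 && 0.4 <= fit$ci[2])

  # independent score: CI covers zero
  fit0 <- cognitive_association(rnorm(n), rsfc, age)
  expect_true(fit0$ci[1] <= 0 && 0 <= fit0$ci[2])

  # duplicating the dataset leaves the point estimate unchanged
  fit2 <- cognitive_association(rep(score, 2), rep(rsfc, 2), rep(age, 2))
  expect_equal(fit2$coefficient, fit$coefficient, tolerance = 1e-12)

  # rsFC perfectly explained by age is not identifiable
  expect_error(cognitive_association(score, 2 - 0.01 * age, age),
               class = "agenet_design_error")
})
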