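test_that("edge counts and edge indexing agree and invert", {
  expect_identical(edge_count(2), 1L)
  expect_identical(edge_count(10), 45L)
  expect_error(edge_count(0), class = "agenet_invalid_argument")
  expect_error(edge_count(2.5), class = "agenet_invalid_argument")

  for (N in c(2, 3, 7, 20, 113, 300)) {
    idx <- edge_index(N)
    expect_identical(nrow(idx), edge_count(N))
    # bijection (i, j) <-> edge position
    expect_identical(pair_to_edge(idx$i, idx$j, N), seq_len(nrow(idx)))
    # symmetric in the pair order
    expect_identical(pair_to_edge(idx$j, idx$i, N), seq_len(nrow(idx)))
  }
  expect_error(pair_to_edge(0, 0, 5), class = "agenet_invalid_argument")
  expect_error(pair_to_edge(0, 5, 5), class = "agenet_invalid_argument")
})

test_that("edge-vector and matrix views round-trip on symmetric matrices", {
  set.seed(42)
  for (N in c(2, 5, 17)) {
    M <- matrix(rnorm(N * N), N, N)
    M <- M + t(M); diag(M) <- 0
    v <- agenet:::matrix_to_edges(M)
    expect_equal(agenet:::edges_to_matrix(v, N), M)
    v2 <- rnorm(edge_count(N))
    expect_equal(agenet:::matrix_to_edges(agenet:::edges_to_matrix(v2, N)), v2)
  }
})

test_that("fisher_z is atanh with clipping and odd symmetry", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  # inverse property on a wide z range
  z <- seq(-5, 5, length.out = 101)
  expect_equal(fisher_z(tanh(z)), z, tolerance = 1e-12)
  # clipping keeps extreme correlations finite
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1.2), -atanh(1 - 1e-7))
  expect_error(fisher_z("a"), class = "agenet_invalid_argument")
})

test_that("time-series connectomes handle perfect, null, and degenerate columns", {
  set.seed(7)
  T_len <- 400
  x <- rnorm(T_len)
  ts <- cbind(x, x, -x, rnorm(T_len), const = rep(1, T_len))
  Z <- timeseries_to_connectome(ts)
  expect_equal(Z[1, 2], atanh(1 - 1e-7))          # identical columns, clipped
  expect_equal(Z[1, 3], -atanh(1 - 1e-7))         # a column and its negation
  expect_lt(abs(Z[1, 4]), 4 / sqrt(T_len))        # independent noise: z near 0
  expect_true(all(is.na(Z[5, ])))                 # zero variance -> missing edges
  expect_true(all(is.na(diag(Z))))
  expect_equal(Z, t(Z))
  expect_error(timeseries_to_connectome(ts[1:2, ]), class = "agenet_invalid_argument")
})

test_that("qc_filter removes high-missing and low-variation subjects, preserving order", {
  N <- 8; E <- edge_count(N)
  set.seed(1)
  vals <- matrix(rnorm(4 * E, 0, 0.3), 4, E)
  vals[2, seq_len(E / 2)] <- NA          # 50% missing
  vals[3, ] <- 0.5                       # constant: sd = 0
  stack <- connectome_stack(vals, N, subject_ids = paste0("s", 1:4))

  kept <- suppressMessages(qc_filter(stack, max_missing_ratio = 0.1,
                                     variation_bounds = c(0.01, 10)))
  expect_identical(kept$subject_ids, c("s1", "s4"))
  log <- attr(kept, "qc_log")
  expect_identical(unname(log[c("removed_missing", "removed_variation")]), c(1L, 1L))

  # loose thresholds on a complete stack: no-op
  clean <- connectome_stack(matrix(rnorm(3 * E, 0, 0.3), 3, E), N)
  expect_equal(suppressMessages(qc_filter(clean))$values, clean$values)

  expect_error(suppressMessages(qc_filter(stack, max_missing_ratio = 0,
                                          variation_bounds = c(5, 6))),
               class = "agenet_empty_cohort")
})

test_that("mean imputation fills missing edges and is a fixed point of edge means", {
  N <- 6; E <- edge_count(N)
  vals <- matrix(rnorm(3 * E), 3, E)
  vals[3, 1] <- NA
  vals[1:2, 1] <- c(1, 3)
  stack <- connectome_stack(vals, N)
  imp <- impute_missing(stack)
  expect_equal(imp$values[3, 1], 2)                 # mean of {1, 3}
  expect_false(any(imp$missing))
  expect_equal(imp$values[, -1], vals[, -1])        # untouched elsewhere

  # random missingness: per-edge means unchanged by imputation
  set.seed(3)
  v2 <- matrix(rnorm(40 * E), 40, E)
  m2 <- matrix(runif(40 * E) < 0.05, 40, E)
  v2[m2] <- NA
  st2 <- connectome_stack(v2, N)
  imp2 <- impute_missing(st2)
  expect_equal(colMeans(imp2$values), colMeans(v2, na.rm = TRUE), tolerance = 1e-12)
  expect_true(all(is.finite(colMeans(imp2$values))))

  # an edge missing everywhere cannot be imputed
  v3 <- v2; v3[, 2] <- NA
  expect_error(impute_missing(connectome_stack(v3, N)),
               class = "agenet_unimputable_edge")

  # qc then impute leaves a complete stack
  piped <- impute_missing(suppressMessages(qc_filter(st2)))
  expect_false(any(piped$missing))
})

test_that("connectome and covariate text formats round-trip", {
  coh <- make_null_cohort(n = 6, N = 5, seed = 9)
  stack <- coh$stack
  stack$values[2, 3] <- NA; stack$missing[2, 3] <- TRUE

  f <- withr::local_tempfile(fileext = ".csv")
  write_connectome_long(stack, f)
  back <- read_connectome_long(f)
  expect_equal(back$values, stack$values, tolerance = 1e-12)
  expect_identical(back$subject_ids, stack$subject_ids)
  expect_identical(which(back$missing), which(stack$missing))

  # square-matrix layout with manifest
  dir <- withr::local_tempdir()
  for (s in seq_along(stack$subject_ids)) {
    write.table(subject_matrix(coh$stack, s), file.path(dir, paste0("m", s, ".csv")),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  writeLines(c("subject_id,file",
               paste0(stack$subject_ids, ",m", seq_along(stack$subject_ids), ".csv")),
             file.path(dir, "manifest.csv"))
  back2 <- read_connectome_matrices(file.path(dir, "manifest.csv"))
  expect_equal(back2$values, coh$stack$values, tolerance = 1e-12)

  fc <- withr::local_tempfile(fileext = ".csv")
  write_covariates(coh$subjects, fc)
  subj <- read_covariates(fc)
  expect_equal(subj$age, coh$subjects$age, tolerance = 1e-12)
  expect_identical(subj$sex, coh$subjects$sex)
})

test_that("parcellation tables are validated", {
  parc <- synthetic_parcellation(14)
  expect_s3_class(parc, "parcellation")
  expect_identical(parc$node_id, 0:13)
  f <- withr::local_tempfile(fileext = ".csv")
  write_parcellation(parc, f)
  expect_equal(read_parcellation(f), parc)

  bad <- parc; bad$node_id[2] <- 5L
  expect_error(as_parcellation(bad), class = "agenet_invalid_argument")
  bad2 <- as.data.frame(parc); bad2$network[1] <- ""
  expect_error(as_parcellation(bad2), class = "agenet_invalid_argument")
})
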