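test_that("subnetwork score is the shrunken intra-edge weight sum", {
  W <- matrix(2, 3, 3); diag(W) <- 0
  expect_equal(subnetwork_score(W, 0:2, lambda = 1.3), 3 * (2 - 1.3))
  expect_lt(subnetwork_score(matrix(0, 5, 5), 0:3, lambda = 0.5), 0)
  Wr <- make_null_W(8, seed = 2, masked = FALSE)
  expect_equal(subnetwork_score(Wr, c(1, 3, 6), lambda = 0),
               Wr[2, 4] + Wr[2, 7] + Wr[4, 7])
  expect_error(subnetwork_score(Wr, c(0, 99)), class = "agenet_invalid_argument")
  expect_error(subnetwork_score(Wr, 3), class = "agenet_invalid_argument")
  expect_error(subnetwork_score(Wr, 0:2, lambda = -1), class = "agenet_invalid_argument")

  # score is non-increasing in lambda for a fixed set
  lams <- seq(0, 3, by = 0.5)
  scores <- vapply(lams, function(l) subnetwork_score(Wr, 0:4, l), numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("density is the fraction of significant intra-set edges", {
  full <- matrix(5, 10, 10); diag(full) <- 0
  expect_equal(subnetwork_density(full, 0:9), 1)
  expect_equal(subnetwork_density(matrix(0, 10, 10), 0:9), 0)
  # 22 of 45 edges significant in a 10-node set
  w <- c(rep(2, 22), rep(0.5, 23))
  W <- agenet:::edges_to_matrix(w, 10)
  expect_equal(subnetwork_density(W, 0:9, p_thresh = 0.05), 22 / 45)
})

test_that("the exhaustive oracle finds dominant structures and refuses big graphs", {
  # one dominant triangle
  W <- matrix(0.1, 6, 6); diag(W) <- 0
  W[1:3, 1:3] <- 4; diag(W) <- 0
  best <- brute_force_best_subgraph(W, lambda = 1)
  expect_identical(best$nodes, 0:2)

  # all-equal weights above lambda: adding any node increases the score
  We <- matrix(2, 7, 7); diag(We) <- 0
  expect_identical(brute_force_best_subgraph(We, lambda = 1)$nodes, 0:6)

  expect_null(brute_force_best_subgraph(matrix(0, 5, 5), lambda = 0.1))
  expect_error(brute_force_best_subgraph(matrix(0, 20, 20)),
               class = "agenet_invalid_argument")
})

test_that("greedy extraction recovers planted blocks and reports them strongest-first", {
  W <- make_planted_W(20, block = 4:15, w_in = 3, bg_sd = 0.3, seed = 5)
  ex <- extract_subnetworks(W, lambda = 1.3)
  expect_identical(ex$subnetworks[[1]]$nodes, 4:15)
  expect_equal(ex$subnetworks[[1]]$density, 1)

  # matches the exhaustive optimum on the same instance (within guard size)
  W14 <- make_planted_W(14, block = 2:9, w_in = 3, bg_sd = 0.3, seed = 6)
  bf <- brute_force_best_subgraph(W14, lambda = 1.3)
  ex14 <- extract_subnetworks(W14, lambda = 1.3, min_size = 2)
  expect_equal(ex14$subnetworks[[1]]$score, bf$score, tolerance = 1e-10)
  expect_identical(ex14$subnetworks[[1]]$nodes, bf$nodes)

  # two disjoint planted blocks of unequal strength, stronger first
  W2 <- make_planted_W(30, block = 0:9, w_in = 4, bg_sd = 0.2, seed = 7)
  W2[21:30, 21:30] <- 2.5; diag(W2) <- 0
  ex2 <- extract_subnetworks(W2, lambda = 1.3)
  expect_identical(ex2$subnetworks[[1]]$nodes, 0:9)
  expect_identical(ex2$subnetworks[[2]]$nodes, 20:29)
  expect_gt(ex2$subnetworks[[1]]$score, ex2$subnetworks[[2]]$score)
})

test_that("extraction returns disjoint subnetworks with non-decreasing greedy traces", {
  for (s in 1:5) {
    W <- make_null_W(25, seed = s, masked = FALSE)
    ex <- extract_subnetworks(W, lambda = 0.8, min_size = 2)
    nodes <- unlist(lapply(ex$subnetworks, `[[`, "nodes"))
    expect_identical(anyDuplicated(nodes), 0L)
    for (tr in ex$trace) expect_true(all(diff(tr) > 0))
    for (sn in ex$subnetworks) expect_gt(sn$score, 0)
  }
})

test_that("background-only weights rarely yield a subnetwork of meaningful size", {
  found <- vapply(1:20, function(s) {
    W <- make_null_W(40, seed = 100 + s)   # masked null -log10(p) weights
    length(extract_subnetworks(W, lambda = default_lambda(), min_size = 5)$subnetworks) > 0
  }, logical(1))
  expect_lte(mean(found), 0.05)
  expect_length(extract_subnetworks(matrix(0, 10, 10))$subnetworks, 0)
})

test_that("greedy extraction tracks the exhaustive optimum on random instances", {
  attained <- ratio <- numeric(0)
  for (s in 1:30) {
    N <- sample(10:14, 1)
    W <- make_null_W(N, seed = 200 + s, masked = FALSE)
    if (s %% 3 == 0) {                    # occasionally add real structure
      blk <- sample(N, 5) - 1L
      W[blk + 1, blk + 1] <- W[blk + 1, blk + 1] + 1.5; diag(W) <- 0
    }
    bf <- brute_force_best_subgraph(W, lambda = 1)
    ex <- extract_subnetworks(W, lambda = 1, min_size = 2)
    g <- if (length(ex$subnetworks)) ex$subnetworks[[1]]$score else 0
    b <- if (is.null(bf)) 0 else bf$score
    if (b == 0) { attained <- c(attained, g == 0); next }
    attained <- c(attained, abs(g - b) < 1e-9)
    ratio <- c(ratio, g / b)
  }
  expect_gte(mean(attained), 0.8)
  expect_gte(min(ratio), 0.95)
})
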