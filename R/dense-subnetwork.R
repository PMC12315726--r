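# Adaptive dense subnetwork extraction from the -log10(p) inference matrix.
#
# Objective: for a node set S, T(G(S)) = sum over intra-S pairs of (w_ij -
# lambda). The per-edge penalty lambda is an l0-style shrinkage: a subset
# scores positively only when its intra-edge weights beat lambda on average,
# so sparse or weak subsets are rejected and false-positive edges are shrunk
# away. Extraction is greedy (seed at the strongest edge, grow by best gain,
# refine by removal/swap passes) with peel-off of accepted node sets, which
# enforces disjoint discoveries. An exhaustive enumerator over small graphs
# serves as the validation oracle.

#' Default edge-level shrinkage threshold
#'
#' `-log10(0.05 * adjust)`: the weight an edge needs before it contributes
#' positively to a subnetwork score.
#'
#' @param adjust Multiplier on the 0.05 reference level.
#' @return Threshold in `-log10(p)` units (1.301 at `adjust = 1`).
#' @export
default_lambda <- function(adjust = 1) -log10(0.05 * adjust)

#' Shrunken score of a node set
#'
#' `T(G(S)) = sum_{i<j in S} (w_ij - lambda)`.
#'
#' @param W An `inference_matrix` or nonnegative symmetric matrix.
#' @param S Integer vector of 0-based node ids, at least 2.
#' @param lambda Per-edge shrinkage penalty (>= 0).
#' @return Numeric score.
#' @export
subnetwork_score <- function(W, S, lambda = default_lambda()) {
  Wm <- as_w_matrix(W)
  S <- unique(as.integer(S))
  if (length(S) < 2L) stop_invalid("S needs at least 2 nodes")
  if (any(S < 0 | S >= nrow(Wm))) stop_invalid("S contains unknown nodes")
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  sub <- Wm[S + 1L, S + 1L]
  sum(sub[upper.tri(sub)] - lambda)
}

#' Density of age-related connections within a node set
#'
#' Fraction of intra-S edges whose edge-level p-value clears `p_thresh`
#' (equivalently whose weight exceeds `-log10(p_thresh)`).
#'
#' @inheritParams subnetwork_score
#' @param p_thresh Edge-level significance threshold (default 0.05).
#' @return Fraction in [0, 1].
#' @export
subnetwork_density <- function(W, S, p_thresh = 0.05) {
  Wm <- as_w_matrix(W)
  S <- unique(as.integer(S))
  if (length(S) < 2L) stop_invalid("S needs at least 2 nodes")
  sub <- Wm[S + 1L, S + 1L]
  mean(sub[upper.tri(sub)] > -log10(p_thresh))
}

# Package a node set into a subnetwork record.
make_subnetwork <- function(Wm, S, lambda, p_thresh) {
  sub <- Wm[S + 1L, S + 1L]
  ut <- sub[upper.tri(sub)]
  structure(list(nodes = sort(as.integer(S)),
                 score = sum(ut - lambda),
                 density = mean(ut > -log10(p_thresh)),
                 n_edges_sig = sum(ut > -log10(p_thresh))),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d nodes, score %.3f, density %.3f (%d significant edges)",
              length(x$nodes), x$score, x$density, x$n_edges_sig))
  if (!is.null(x$p_value)) cat(sprintf(", permutation p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

# Greedy growth + local refinement from a seed edge. Returns NULL if no
# positive-score set emerges. `avail` is a logical over 1-based node indices.
grow_from_seed <- function(Wm, avail, seed_pair, lambda, max_iter = 500L) {
  N <- nrow(Wm)
  inS <- rep(FALSE, N)
  inS[seed_pair] <- TRUE
  cs <- Wm[, seed_pair[1]] + Wm[, seed_pair[2]]  # sum of weights into S
  score <- Wm[seed_pair[1], seed_pair[2]] - lambda
  trace <- score
  tol <- 1e-12

  # Phase 1: pure greedy growth while the best addition has positive gain.
  repeat {
    size <- sum(inS)
    cand <- which(avail & !inS)
    if (!length(cand)) break
    gains <- cs[cand] - lambda * size
    b <- which.max(gains)            # which.max takes the first (lowest id) tie
    if (gains[b] <= tol) break
    v <- cand[b]
    inS[v] <- TRUE
    cs <- cs + Wm[, v]
    score <- score + gains[b]
    trace <- c(trace, score)
  }

  # Phase 2: removal / addition / swap passes until no move improves T.
  for (it in seq_len(max_iter)) {
    size <- sum(inS)
    members <- which(inS)
    # contribution of member u: cs[u] - lambda * (size - 1); removing u
    # changes the score by minus that contribution
    contrib <- cs[members] - lambda * (size - 1)
    worst <- which.min(contrib)
    if (size > 2L && contrib[worst] < -tol) {
      u <- members[worst]
      inS[u] <- FALSE
      cs <- cs - Wm[, u]
      score <- score - contrib[worst]
      trace <- c(trace, score)
      next
    }
    cand <- which(avail & !inS)
    if (length(cand)) {
      gains <- cs[cand] - lambda * size
      b <- which.max(gains)
      if (gains[b] > tol) {
        v <- cand[b]
        inS[v] <- TRUE
        cs <- cs + Wm[, v]
        score <- score + gains[b]
        trace <- c(trace, score)
        next
      }
      # swap: replace the weakest member u by the best outsider v;
      # delta = (cs[v] - W[v,u] - lambda*(size-1)) - (cs[u] - lambda*(size-1))
      u <- members[worst]
      deltas <- cs[cand] - Wm[cand, u] - cs[u]
      b <- which.max(deltas)
      if (deltas[b] > tol) {
        v <- cand[b]
        inS[u] <- FALSE; cs <- cs - Wm[, u]
        inS[v] <- TRUE;  cs <- cs + Wm[, v]
        score <- score + deltas[b]
        trace <- c(trace, score)
        next
      }
    }
    break
  }
  if (score <= tol) return(NULL)
  list(nodes0 = which(inS) - 1L, score = score, trace = trace)
}

#' Extract dense age-related subnetworks
#'
#' Repeatedly: seed at the strongest remaining edge, greedily add the node
#' with the best score gain while positive, refine by single-node
#' removal/addition/swap passes, and — if the refined set has at least
#' `min_size` nodes and positive score — accept it and peel its nodes off
#' (zeroing their rows/columns) before searching again. Several top seed
#' edges are tried per round and the best acceptable result kept; ties break
#' deterministically toward lower node ids.
#'
#' @param W An `inference_matrix` or nonnegative symmetric matrix.
#' @param lambda Per-edge shrinkage penalty (default [default_lambda()]).
#' @param min_size Minimum accepted subnetwork size (default 5; smaller sets
#'   are dominated by the permutation null).
#' @param max_subnetworks Stop after this many discoveries (default 10).
#' @param p_thresh Edge threshold used for the reported densities.
#' @param n_restarts Seed edges examined per round before committing (default
#'   5); more restarts trade time for a better local optimum.
#' @return An `extraction_result`: list with `subnetworks` (disjoint, in
#'   decreasing score order), `lambda`, and a per-round `trace` of greedy
#'   scores.
#' @export
extract_subnetworks <- function(W, lambda = default_lambda(), min_size = 5L,
                                max_subnetworks = 10L, p_thresh = 0.05,
                                n_restarts = 5L) {
  Wm <- as_w_matrix(W)
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  N <- nrow(Wm)
  avail <- rep(TRUE, N)
  subnets <- list()
  traces <- list()
  while (length(subnets) < max_subnetworks) {
    # candidate seeds: edges with weight above lambda among available nodes
    Wa <- Wm
    Wa[!avail, ] <- 0; Wa[, !avail] <- 0
    ut <- upper.tri(Wa)
    cand <- which(ut & Wa > lambda)
    if (!length(cand)) break
    ord <- cand[order(-Wa[cand], cand)]
    best <- NULL
    tried <- 0L
    for (e in ord) {
      seed_pair <- c((e - 1L) %% N + 1L, (e - 1L) %/% N + 1L)
      g <- grow_from_seed(Wm * outer(avail, avail), avail, seed_pair, lambda)
      tried <- tried + 1L
      if (!is.null(g) && length(g$nodes0) >= min_size) {
        if (is.null(best) || g$score > best$score + 1e-12) best <- g
      }
      if (!is.null(best) && tried >= n_restarts) break
    }
    if (is.null(best)) break
    sn <- make_subnetwork(Wm, best$nodes0, lambda, p_thresh)
    subnets[[length(subnets) + 1L]] <- sn
    traces[[length(traces) + 1L]] <- best$trace
    avail[best$nodes0 + 1L] <- FALSE          # peel-off: remove the nodes
  }
  ord <- order(-vapply(subnets, `[[`, numeric(1), "score"))
  structure(list(subnetworks = subnets[ord], lambda = lambda,
                 min_size = as.integer(min_size), p_thresh = p_thresh,
                 trace = traces[ord]),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("extraction_result: %d subnetwork(s) at lambda = %.3f\n",
              length(x$subnetworks), x$lambda))
  for (k in seq_along(x$subnetworks)) {
    cat(sprintf("  [%d] ", k)); print(x$subnetworks[[k]])
  }
  invisible(x)
}

#' Exhaustive best-subgraph oracle
#'
#' Scores every node subset of size >= 2 and returns the maximizer of
#' `T(G(S))`; ties break toward smaller sets, then lexicographically smaller
#' node ids. Refuses graphs above `max_nodes` (the enumeration is 2^N).
#'
#' @inheritParams subnetwork_score
#' @param max_nodes Combinatorial guard (default 15).
#' @param p_thresh Edge threshold for the reported density.
#' @return A `subnetwork`, or `NULL` when no subset scores positively.
#' @export
brute_force_best_subgraph <- function(W, lambda = default_lambda(),
                                      max_nodes = 15L, p_thresh = 0.05) {
  Wm <- as_w_matrix(W)
  N <- nrow(Wm)
  if (N > max_nodes) stop_invalid("N = ", N, " exceeds max_nodes = ", max_nodes,
                                  " (exhaustive search refused)")
  subsets <- as.matrix(expand.grid(rep(list(c(0, 1)), N)))
  sizes <- rowSums(subsets)
  keep <- sizes >= 2
  subsets <- subsets[keep, , drop = FALSE]
  sizes <- sizes[keep]
  intra <- rowSums((subsets %*% Wm) * subsets) / 2
  score <- intra - lambda * sizes * (sizes - 1) / 2
  if (max(score) <= 1e-12) return(NULL)
  top <- which(score >= max(score) - 1e-12)
  # tie-break: smaller size, then smaller bitmask (prefers low node ids)
  key <- subsets[top, , drop = FALSE] %*% 2^(0:(N - 1))
  pick <- top[order(sizes[top], key)][1]
  make_subnetwork(Wm, which(subsets[pick, ] == 1) - 1L, lambda, p_thresh)
}
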