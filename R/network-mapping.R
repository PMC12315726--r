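# Interpretation of extracted subnetworks: tallies against predefined
# functional networks, hub identification, and cross-cohort replication.

#' Map a node set onto predefined functional networks
#'
#' @param S Integer vector of 0-based node ids.
#' @param parc A `parcellation` table (see [read_parcellation()]).
#' @return Data frame with one row per predefined network present in the
#'   parcellation: `network`, `n_in_subnetwork`, `network_size`,
#'   `fraction_captured` (share of that network's regions inside `S`).
#' @export
map_to_predefined <- function(S, parc) {
  stopifnot(inherits(parc, "parcellation"))
  S <- unique(as.integer(S))
  if (length(S) && any(!S %in% parc$node_id)) stop_invalid("S contains unknown nodes")
  nets <- sort(unique(parc$network))
  size <- table(factor(parc$network, levels = nets))
  inS <- table(factor(parc$network[parc$node_id %in% S], levels = nets))
  data.frame(network = nets,
             n_in_subnetwork = as.integer(inS),
             network_size = as.integer(size),
             fraction_captured = as.numeric(inS) / as.numeric(size),
             row.names = NULL)
}

#' Node-set overlap between two cohorts' subnetworks
#'
#' @param S1,S2 Integer vectors of 0-based node ids over the same
#'   parcellation.
#' @return List with `overlap` (sorted intersection), `n_overlap`, and
#'   `jaccard` (`|S1 n S2| / |S1 u S2|`).
#' @export
replication_overlap <- function(S1, S2) {
  S1 <- unique(as.integer(S1)); S2 <- unique(as.integer(S2))
  ov <- sort(intersect(S1, S2))
  un <- union(S1, S2)
  list(overlap = ov, n_overlap = length(ov),
       jaccard = if (length(un)) length(ov) / length(un) else 1)
}

#' Identify hub nodes within a subnetwork
#'
#' A hub is a member whose age-related edges reach (essentially) all other
#' members: its significant-edge coverage
#' `#\{j in S : p_ij < p_thresh\} / (|S| - 1)` is at least `coverage_min`
#' (default 1, i.e. connected to every other member).
#'
#' @param W An `inference_matrix` or nonnegative symmetric matrix.
#' @param S Integer vector of 0-based node ids (at least 2).
#' @param p_thresh Edge-level significance threshold.
#' @param coverage_min Required coverage in (0, 1].
#' @return Integer vector of hub node ids (possibly empty), with per-node
#'   coverages attached as attribute `"coverage"`.
#' @export
identify_hubs <- function(W, S, p_thresh = 0.05, coverage_min = 1) {
  Wm <- as_w_matrix(W)
  S <- unique(as.integer(S))
  if (length(S) < 2L) stop_invalid("S needs at least 2 nodes")
  if (coverage_min <= 0 || coverage_min > 1) stop_invalid("coverage_min must be in (0, 1]")
  sub <- Wm[S + 1L, S + 1L] > -log10(p_thresh)
  diag(sub) <- NA
  cov <- rowMeans(sub, na.rm = TRUE)
  hubs <- S[cov >= coverage_min]
  structure(sort(hubs), coverage = stats::setNames(cov, S))
}

#' Hypergeometric p-value for a cross-cohort node overlap
#'
#' Probability of an overlap at least this large if `S2` were a uniformly
#' random subset of the `N` regions, given the sizes of `S1` and `S2`. This is
#' a simple enrichment summary for replication reports (it ignores the
#' spatial/statistical structure of extraction).
#'
#' @param S1,S2 0-based node id vectors.
#' @param N Total number of regions in the parcellation.
#' @return Upper-tail hypergeometric p-value.
#' @export
overlap_hypergeom_pvalue <- function(S1, S2, N) {
  S1 <- unique(as.integer(S1)); S2 <- unique(as.integer(S2))
  k <- length(intersect(S1, S2))
  stats::phyper(k - 1, length(S1), N - length(S1), length(S2), lower.tail = FALSE)
}
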