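#' Number of unique edges in an N-node connectome
#'
#' An undirected functional connectome on `N` regions of interest has
#' `N(N-1)/2` distinct region pairs. For the 246-region Brainnetome atlas this
#' is 30,135 edges.
#'
#' @param N Integer node (region) count, at least 1.
#' @return Integer edge count `N(N-1)/2`.
#' @examples
#' edge_count(246)
#' @export
edge_count <- function(N) {
  if (length(N) != 1L || !is.numeric(N) || !is.finite(N) || N != round(N) || N < 1) {
    stop_invalid("N must be a single integer >= 1")
  }
  as.integer(round(N * (N - 1) / 2))
}

#' Canonical edge ordering for an N-node connectome
#'
#' Edges are the node pairs `(i, j)` with `i < j`, enumerated in lexicographic
#' order over 0-based node ids: (0,1), (0,2), ..., (0,N-1), (1,2), ...
#' This ordering defines the column layout of a [connectome_stack()].
#'
#' @param N Node count.
#' @return A data.frame with integer columns `i` and `j` (0-based node ids)
#'   and `edge_count(N)` rows.
#' @export
edge_index <- function(N) {
  E <- edge_count(N)
  if (N == 1L) return(data.frame(i = integer(0), j = integer(0)))
  i <- rep.int(0:(N - 2), times = (N - 1):1)
  j <- sequence((N - 1):1, from = 1:(N - 1))
  data.frame(i = as.integer(i), j = as.integer(j))[seq_len(E), , drop = FALSE]
}

#' Map a node pair to its position in the canonical edge ordering
#'
#' @param i,j 0-based node ids (vectors allowed); order within a pair is
#'   irrelevant but `i != j` is required.
#' @param N Node count.
#' @return 1-based edge positions into [edge_index()] / stack columns.
#' @export
pair_to_edge <- function(i, j, N) {
  edge_count(N)
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo < 0 | hi >= N | lo == hi)) stop_invalid("node ids out of range or i == j")
  as.integer(lo * N - lo * (lo + 1) / 2 + (hi - lo))
}

# Edge vector -> symmetric N x N matrix (diagonal = `diag`, default 0).
edges_to_matrix <- function(v, N, diag = 0) {
  idx <- edge_index(N)
  M <- matrix(diag, N, N)
  M[cbind(idx$i + 1L, idx$j + 1L)] <- v
  M[cbind(idx$j + 1L, idx$i + 1L)] <- v
  M
}

# Symmetric matrix -> edge vector in canonical order (diagonal dropped).
matrix_to_edges <- function(M) {
  N <- nrow(M)
  stopifnot(ncol(M) == N)
  idx <- edge_index(N)
  M[cbind(idx$i + 1L, idx$j + 1L)]
}

#' Fisher z-transform of a correlation
#'
#' `atanh(r)`, with |r| at or beyond 1 clipped to `1 - clip` so that downstream
#' regression stays finite.
#'
#' @param r Correlation value(s).
#' @param clip Clipping margin; values with `|r| >= 1` become `sign(r) * (1 - clip)`.
#' @return Fisher z-value(s).
#' @examples
#' fisher_z(0.5)
#' @export
fisher_z <- function(r, clip = 1e-7) {
  if (!is.numeric(r)) stop_invalid("r must be numeric")
  r <- ifelse(abs(r) >= 1, sign(r) * (1 - clip), r)
  atanh(r)
}

#' Build one subject's connectome from a region time-series matrix
#'
#' Pearson-correlates every pair of columns and Fisher z-transforms the result.
#' Zero-variance columns yield missing (NA) edges rather than an error.
#'
#' @param ts Numeric `T x N` matrix: T time points, N regions.
#' @param clip Passed to [fisher_z()].
#' @return Symmetric `N x N` matrix of Fisher z-values; diagonal is `NA`
#'   (unused sentinel); edges touching a zero-variance region are `NA`.
#' @export
timeseries_to_connectome <- function(ts, clip = 1e-7) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop_invalid("need at least 3 time points")
  sds <- apply(ts, 2, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  R <- suppressWarnings(stats::cor(ts))
  Z <- fisher_z(R, clip = clip)
  Z[bad, ] <- NA_real_
  Z[, bad] <- NA_real_
  diag(Z) <- NA_real_
  Z
}

#' Construct a connectome stack
#'
#' The stack is the package's edge-major container for a cohort of subject
#' connectomes: a `subjects x edges` matrix of Fisher-z values in the canonical
#' [edge_index()] ordering, plus a logical missingness mask.
#'
#' @param values `subjects x edges` numeric matrix.
#' @param N Node count (edges must equal `edge_count(N)`).
#' @param subject_ids Character vector of subject identifiers.
#' @param missing Optional logical mask, same shape as `values`; `NA`s in
#'   `values` are always treated as missing.
#' @return An object of class `connectome_stack` with fields `values`,
#'   `missing`, `N`, `subject_ids`.
#' @export
connectome_stack <- function(values, N, subject_ids = NULL, missing = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != edge_count(N)) {
    stop_invalid("values has ", ncol(values), " columns; expected edge_count(",
                 N, ") = ", edge_count(N))
  }
  n <- nrow(values)
  subject_ids <- as.character(subject_ids %||% sprintf("sub%04d", seq_len(n)))
  if (length(subject_ids) != n) stop_invalid("subject_ids length mismatch")
  if (is.null(missing)) missing <- matrix(FALSE, n, ncol(values))
  missing <- missing | is.na(values)
  values[missing] <- NA_real_
  if (any(!is.finite(values[!missing]))) stop_invalid("non-finite non-missing values")
  structure(list(values = values, missing = missing, N = as.integer(N),
                 subject_ids = subject_ids),
            class = "connectome_stack")
}

#' @export
print.connectome_stack <- function(x, ...) {
  cat(sprintf("connectome_stack: %d subjects x %d edges (N = %d nodes), %.2f%% missing\n",
              nrow(x$values), ncol(x$values), x$N, 100 * mean(x$missing)))
  invisible(x)
}

#' @export
dim.connectome_stack <- function(x) dim(x$values)

#' Extract one subject's connectome as a symmetric matrix
#'
#' @param stack A [connectome_stack()].
#' @param subject Subject id (character) or row index.
#' @return Symmetric `N x N` matrix (diagonal 0, missing edges `NA`).
#' @export
subject_matrix <- function(stack, subject) {
  s <- if (is.character(subject)) match(subject, stack$subject_ids) else subject
  if (is.na(s) || s < 1 || s > nrow(stack$values)) stop_invalid("unknown subject")
  edges_to_matrix(stack$values[s, ], stack$N)
}

#' Quality-control filter on a connectome stack
#'
#' Retains subjects whose fraction of missing edges does not exceed
#' `max_missing_ratio` and whose per-subject edge standard deviation (over
#' non-missing edges) lies inside `variation_bounds`. Mirrors cohort-level QC
#' where subjects with a low missing ratio and an acceptable variation are
#' kept. Counts removed per criterion are attached as attribute `"qc_log"` and
#' printed via message.
#'
#' @param stack A [connectome_stack()].
#' @param max_missing_ratio Maximum tolerated missing fraction (default 0.1).
#' @param variation_bounds Length-2 numeric `(low, high)` bounds on the
#'   per-subject edge SD (default `c(0.01, 2)`).
#' @param quiet Suppress the summary message.
#' @return The filtered stack (subject order preserved).
#' @export
qc_filter <- function(stack, max_missing_ratio = 0.1,
                      variation_bounds = c(0.01, 2), quiet = FALSE) {
  stopifnot(inherits(stack, "connectome_stack"))
  if (max_missing_ratio < 0 || max_missing_ratio > 1 ||
      any(!is.finite(variation_bounds)) || length(variation_bounds) != 2L) {
    stop_invalid("bad QC thresholds")
  }
  miss_frac <- rowMeans(stack$missing)
  sds <- apply(stack$values, 1, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds)] <- 0
  fail_miss <- miss_frac > max_missing_ratio
  fail_var <- sds < variation_bounds[1] | sds > variation_bounds[2]
  keep <- !fail_miss & !fail_var
  if (!any(keep)) {
    stop(structure(class = c("agenet_empty_cohort", "error", "condition"),
                   list(message = "QC removed every subject", call = sys.call())))
  }
  log <- c(n_in = nrow(stack$values), removed_missing = sum(fail_miss),
           removed_variation = sum(fail_var & !fail_miss), n_out = sum(keep))
  if (!quiet) {
    message(sprintf("qc_filter: kept %d/%d subjects (%d high-missing, %d out-of-range variation)",
                    log["n_out"], log["n_in"], log["removed_missing"], log["removed_variation"]))
  }
  out <- connectome_stack(stack$values[keep, , drop = FALSE], stack$N,
                          stack$subject_ids[keep],
                          stack$missing[keep, , drop = FALSE])
  attr(out, "qc_log") <- log
  out
}

#' Mean-impute missing edges across subjects
#'
#' Each missing entry is replaced by the across-subject mean of that edge;
#' non-missing entries are untouched and the mask is cleared.
#'
#' @param stack A [connectome_stack()].
#' @return Stack with no missing entries.
#' @export
impute_missing <- function(stack) {
  stopifnot(inherits(stack, "connectome_stack"))
  if (!any(stack$missing)) return(stack)
  v <- stack$values
  n_obs <- colSums(!stack$missing)
  if (any(n_obs == 0)) {
    bad <- which(n_obs == 0)
    stop(structure(class = c("agenet_unimputable_edge", "error", "condition"),
                   list(message = paste0("edges missing for all subjects: ",
                                         paste(utils::head(bad, 10), collapse = ", "),
                                         if (length(bad) > 10) " ..."),
                        call = sys.call())))
  }
  mu <- colSums(ifelse(stack$missing, 0, v), na.rm = TRUE) / n_obs
  idx <- which(stack$missing, arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  connectome_stack(v, stack$N, stack$subject_ids)
}
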