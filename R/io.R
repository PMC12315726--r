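# Text-format I/O for connectome stacks, parcellation tables, and covariates.
# Two connectome layouts are supported: a long edge table
# (subject_id,i,j,z[,missing]) and one square matrix per subject plus a
# manifest listing subject_id,file.

#' Write a connectome stack as a long-format edge table
#'
#' Columns: `subject_id, i, j, z` with 0-based node ids; missing edges are
#' written with empty `z`.
#'
#' @param stack A [connectome_stack()].
#' @param path Output file.
#' @param sep Field separator (default comma).
#' @export
write_connectome_long <- function(stack, path, sep = ",") {
  idx <- edge_index(stack$N)
  n <- nrow(stack$values)
  df <- data.frame(
    subject_id = rep(stack$subject_ids, each = nrow(idx)),
    i = rep(idx$i, times = n),
    j = rep(idx$j, times = n),
    z = as.vector(t(stack$values))
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a long-format connectome edge table
#'
#' @param path File with header `subject_id,i,j,z`.
#' @param N Node count; inferred from `max(j) + 1` when omitted.
#' @param sep Field separator.
#' @return A [connectome_stack()]; absent or empty `z` entries become missing.
#' @export
read_connectome_long <- function(path, N = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c(subject_id = "character"))
  need <- c("subject_id", "i", "j", "z")
  if (!all(need %in% names(df))) stop_invalid("expected header subject_id,i,j,z")
  N <- N %||% (max(df$j) + 1L)
  subs <- unique(df$subject_id)
  E <- edge_count(N)
  vals <- matrix(NA_real_, length(subs), E)
  e <- pair_to_edge(df$i, df$j, N)
  s <- match(df$subject_id, subs)
  vals[cbind(s, e)] <- df$z
  connectome_stack(vals, N, subs)
}

#' Read per-subject square connectome matrices via a manifest
#'
#' @param manifest Delimited file with header `subject_id,file`; paths are
#'   resolved relative to the manifest's directory.
#' @param sep Field separator of both manifest and matrix files.
#' @return A [connectome_stack()] (diagonals discarded, `NA`s kept as missing).
#' @export
read_connectome_matrices <- function(manifest, sep = ",") {
  man <- utils::read.table(manifest, header = TRUE, sep = sep,
                           colClasses = "character")
  if (!all(c("subject_id", "file") %in% names(man))) {
    stop_invalid("manifest needs columns subject_id,file")
  }
  dir <- dirname(manifest)
  rows <- lapply(man$file, function(f) {
    M <- as.matrix(utils::read.table(file.path(dir, f), header = FALSE, sep = sep))
    matrix_to_edges(M)
  })
  N <- (1 + sqrt(1 + 8 * length(rows[[1]]))) / 2
  connectome_stack(do.call(rbind, rows), as.integer(round(N)), man$subject_id)
}

#' Read a parcellation table
#'
#' Delimited text with header `node_id,label,lobe,network`; node ids must be
#' exactly `0..N-1`. Every node must carry a non-empty network label (an
#' explicit `"unassigned"` token is allowed).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A data.frame of class `parcellation`.
#' @export
read_parcellation <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("integer", "character", "character", "character"))
  as_parcellation(df)
}

#' Validate a parcellation data.frame
#'
#' @param df Data frame with columns `node_id,label,lobe,network`.
#' @return `df`, sorted by node id, with class `parcellation` prepended.
#' @export
as_parcellation <- function(df) {
  need <- c("node_id", "label", "lobe", "network")
  if (!all(need %in% names(df))) stop_invalid("parcellation needs columns ",
                                              paste(need, collapse = ","))
  df <- df[order(df$node_id), need]
  N <- nrow(df)
  if (!identical(as.integer(df$node_id), 0:(N - 1))) {
    stop_invalid("node_id must be exactly 0..N-1 with no gaps or duplicates")
  }
  if (any(!nzchar(df$network) | is.na(df$network))) {
    stop_invalid("every node needs a non-empty network label")
  }
  rownames(df) <- NULL
  class(df) <- c("parcellation", "data.frame")
  df
}

#' @rdname read_parcellation
#' @param parc A `parcellation` data.frame.
#' @export
write_parcellation <- function(parc, path, sep = ",") {
  utils::write.table(parc, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject covariate table
#'
#' One row per subject. Expected columns: `subject_id`, `age`, `sex`, the five
#' imaging confounds `conf1..conf5` (mean framewise displacement and four
#' scanner-position measures), and optionally `fa`, `log_wmh`, and a cognitive
#' battery `cog1..cog9`. Extra columns pass through.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A data.frame of class `subject_table`.
#' @export
read_covariates <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c(subject_id = "character"))
  as_subject_table(df)
}

#' Validate a subject covariate table
#'
#' @param df Data frame; must contain `subject_id`, `age` (> 0) and `sex`
#'   (0/1).
#' @return `df` with class `subject_table` prepended.
#' @export
as_subject_table <- function(df) {
  if (!all(c("subject_id", "age", "sex") %in% names(df))) {
    stop_invalid("subject table needs subject_id, age, sex")
  }
  if (any(df$age <= 0)) stop_invalid("ages must be positive")
  if (!all(df$sex %in% c(0, 1))) stop_invalid("sex must be coded 0/1")
  df$subject_id <- as.character(df$subject_id)
  if (!inherits(df, "subject_table")) class(df) <- c("subject_table", class(df))
  df
}

#' @rdname read_covariates
#' @param subjects A `subject_table`.
#' @export
write_covariates <- function(subjects, path, sep = ",") {
  utils::write.table(subjects, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Check that a stack and a covariate table describe the same subjects in the
# same order.
check_alignment <- function(stack, subjects) {
  if (nrow(subjects) != nrow(stack$values) ||
      !identical(as.character(subjects$subject_id), stack$subject_ids)) {
    stop_invalid("subject table rows must align one-to-one with the stack's subjects")
  }
  invisible(TRUE)
}
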