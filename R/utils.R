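#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derived per-stage seeds: a fixed additive offset per stage keeps every stage
# reproducible from one master seed while decoupling their streams.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(cohort = 0L, qc = 101L, regression = 211L, permutation = 1009L,
               mediation = 2003L, cognition = 3001L, bootstrap = 4001L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("agenet_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
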