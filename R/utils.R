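#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state so callers' RNG streams are unaffected.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed for a pipeline stage
#'
#' Deterministic map from a global seed and a stage index to a stage seed,
#' kept inside the 32-bit integer range.
#'
#' @param seed integer global seed or `NULL`.
#' @param index positive integer stage offset.
#' @return integer seed, or `NULL` if `seed` is `NULL`.
#' @keywords internal
child_seed <- function(seed, index) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) * 1103L + 12289L * index) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
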