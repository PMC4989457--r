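#' @keywords internal
"_PACKAGE"

# Reserved token for missing clinical labels; NA in numeric matrices plays the
# same role for unexpressed-gene PSI values.
MISSING_LABEL <- "MISSING"

#' Run an expression under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a run is fully reproducible from the seeds recorded in
#' its configuration, without clobbering the user's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# Derive a per-iteration seed from a master seed, staying within 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index)) %% .Machine$integer.max)
}

isosig_log <- function(...) {
  message("[isosig] ", ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
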