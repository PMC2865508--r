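#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a top-level seed and a stream name
#'
#' All randomness in the package flows from a single top-level seed; each
#' stage draws from a named substream so that adding a stage never perturbs
#' the draws of another.  The derivation is a small deterministic hash kept
#' below 2^31 - 1 so the result is a valid R integer seed.
#'
#' @param seed integer top-level seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131L)
  as.integer((as.numeric(seed) + h) %% 2147483587)
}

# Evaluate expr with a local RNG state; the caller's global RNG is restored.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a positive integer, got %s", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  invisible(x)
}
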