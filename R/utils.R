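# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All package errors carry a condition class of the form
#' `seqspecies_<kind>_error` so callers can branch on failure modes.
#'
#' @param kind short error kind, e.g. "parse", "schema", "lexicon".
#' @param fmt,... sprintf-style message.
#' @noRd
seqc_abort <- function(kind, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cls <- c(sprintf("seqspecies_%s_error", kind), "seqspecies_error")
  stop(errorCondition(msg, class = cls, call = sys.call(-1)))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library code never
#' perturbs user-level random streams.
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

as_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    seqc_abort("config", "'%s' must be a single non-negative number", name)
  as.integer(x)
}
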