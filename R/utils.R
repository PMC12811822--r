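#' Derive a stage-specific random seed from a global seed
#'
#' All randomness in the package is traceable to a single integer seed.
#' Sub-streams (per generator call, per chain, per bootstrap harness) are
#' derived deterministically from `(seed, key)` so that independent stages
#' never share an RNG stream.
#'
#' @param seed integer global seed.
#' @param key character label of the consuming stage (e.g. `"thermal"`,
#'   `"chain2"`).
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# evaluate `expr` under a temporary RNG state seeded from (seed, key)
with_derived_seed <- function(seed, key, expr) {
  withr::with_seed(derive_seed(seed, key), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# checked scalar accessors for config lists
chk_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop_input("configuration error: '%s' must be an integer >= %d", name, min)
  as.integer(x)
}

chk_pos <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
    stop_input("configuration error: '%s' must be positive", name)
  as.numeric(x)
}
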