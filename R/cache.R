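# In-session cache for gamete tensors and resident equilibria. Both are
# deterministic functions of their parameters (the equilibrium also of its
# seed), so memoisation is transparent: cached and uncached runs agree
# exactly. Keys embed parameters at full double precision.

.migmod_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .migmod_cache, inherits = FALSE)) {
    get(key, envir = .migmod_cache, inherits = FALSE)
  } else {
    NULL
  }
}

cache_set <- function(key, value) {
  assign(key, value, envir = .migmod_cache)
  invisible(value)
}

#' Clear the in-session computation cache
#'
#' Gamete tensors and resident equilibria are memoised per parameterisation.
#' The cache is transparent (cached and fresh results are identical); this is
#' only needed to reclaim memory in long sessions.
#' @return Invisibly, the number of objects dropped.
#' @export
clear_migmod_cache <- function() {
  n <- length(ls(.migmod_cache))
  rm(list = ls(.migmod_cache), envir = .migmod_cache)
  invisible(n)
}
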