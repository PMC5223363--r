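# Run code with a temporary RNG state; restores (or removes) .Random.seed.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Hashes the master seed together with a stage name (and any indices) so
#' each stochastic stage draws from its own named stream. The result always
#' fits a 32-bit integer.
#'
#' @param seed Integer master seed.
#' @param ... Stage name and indices (any hashable values).
#' @return A non-negative integer seed.
#' @export
derive_seed <- function(seed, ...) {
  h <- rlang::hash(list(as.integer(seed), ...))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
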