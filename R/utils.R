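#' Evaluate an expression under a local random seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so generators never leak randomness into (or out of)
#' the session. All package generators route their randomness through this
#' helper: one named seed per call, no global state.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a master seed and a stream index.
# Kept below 2^31 so the result is a valid R integer.
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 9973) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ef <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_ef("%s must lie in [0, 1]", what)
  invisible(x)
}
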