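#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# All stochastic entry points funnel through this so a fixed seed gives
# bit-identical output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a root seed and a task index.
# Keeps results < 2^31 so they remain valid R integers.
split_seed <- function(root, k) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  as.integer((abs(as.numeric(root)) * 48271 + 7919 * as.numeric(k)) %%
               2147483629)
}

# z-standardize a series; degenerate (constant) series are centred only.
standardize <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  list(z = (x - m) / s, mean = m, sd = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
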