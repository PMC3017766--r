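# Internal helpers shared across the package.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb user
# simulations.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Integer check tolerant of doubles holding whole numbers.
is_whole <- function(x) {
  is.numeric(x) && length(x) >= 1 && all(is.finite(x)) && all(x == round(x))
}

stop2 <- function(...) stop(..., call. = FALSE)
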