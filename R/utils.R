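# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed and a stream label,
# kept well inside 32-bit integer range.
child_seed <- function(seed, stream) {
  offsets <- c(
    maps = 11L, latent = 23L, enroll = 37L, cost = 41L, events = 53L,
    demo = 67L, cohort = 71L, planted = 83L, cv = 97L, init = 101L,
    batch = 113L, boot = 127L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 131L + off) %% 2147483399) + 1L
}

# Average-rank percentile in (0, 1]: top value maps to 1 (ascending
# convention; ties share the average rank).
rank_percentile <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  rank(x, ties.method = "average") / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
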