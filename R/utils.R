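# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls never clobber user RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a master seed, keeping them within
# 32-bit integer range.
childSeeds <- function(seed, n, salt = 0L) {
  withSeed(as.integer(seed) + as.integer(salt),
           sample.int(.Machine$integer.max, n))
}

# Smallest 5-smooth ("efficient" FFT) size >= n.
nextFastLength <- function(n) {
  stats::nextn(as.integer(n), factors = c(2L, 3L, 5L))
}

assertFlag <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
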