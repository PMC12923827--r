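## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this so that a
# master seed fully determines all outputs.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically spawn `n` child seeds from a master seed, so that e.g.
# each NMF run or permutation gets its own reproducible stream.
spawnSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonical state names: S01, S02, ...
stateNames <- function(k) sprintf("S%02d", seq_len(k))

# Canonical "<cellType>_S01" row labels for cross-cell-type state stacks.
qualifiedStateNames <- function(cellType, states) paste(cellType, states,
                                                        sep = "_")

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

assertScalar <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single number >= %g", name, min))
  as.numeric(x)
}
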