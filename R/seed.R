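# RNG plumbing.  Every generator in the package is a pure function of its
# (config, seed) arguments: the caller's RNG state is saved, a local seed is
# set, and the state restored on exit.  Per-case seeds are spawned from the
# master seed by fixed arithmetic so that each case is reproducible in
# isolation and all spawned seeds stay below 2^31.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed arithmetic: multiplicative hash folded into
# [0, 2^31 - 2].  'index' distinguishes cases, 'stream' distinguishes roles
# (anatomy vs scanner A vs scanner B, ...).
spawn_seed <- function(master, index, stream = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + 7919 * as.numeric(index) + 104729 * as.numeric(stream)) %% m
  as.integer(x %% (m - 1)) + 1L
}
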