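# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps module-level seeding from perturbing an
# enclosing stochastic process (e.g. the swarm's r1/r2 stream).
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Round half away from zero (all quantities here are nonnegative, so this is
# floor(x + 0.5)); base round() half-to-even would map 0.5 offsets down.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a bounded child seed from a base seed and a stream label so that
# independent components (weight init, subsampling, splits) get distinct but
# reproducible streams. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483629 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
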