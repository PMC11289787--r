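# Internal RNG helpers: run code under a given seed without disturbing the
# caller's RNG state.

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
  force(code)
}

# Deterministic per-run seed below 2^31, distinct across (condition, replicate).
derive_seed <- function(base_seed, condition_index, replicate) {
  (as.numeric(base_seed) + 9973 * condition_index + 389 * replicate) %% 2147483647
}
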