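# Seed plumbing: every stochastic operation in the package evaluates its
# random draws under a locally-set seed and restores the caller's RNG state,
# so identical configs yield bit-identical output regardless of surrounding
# RNG usage.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a component sub-seed from a base seed. Keeps results independent
# across components (jitter, noise, artifacts, ...) so that zeroing one
# component's amplitude does not shift the draws of another; stays < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483629)
}
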