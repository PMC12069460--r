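# Seed plumbing: every stochastic entry point takes a `seed` argument; when
# non-NULL the global RNG state is saved, reseeded, and restored on exit, so
# seeded calls are reproducible without clobbering the caller's stream.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, globalenv())
      } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# deterministic sub-stream seeds below 2^31, derived from one master seed
derive_seed <- function(master, offset) {
  ((as.numeric(master) %% 2147483647) * 48271 + offset * 7919) %% 2147483647
}
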