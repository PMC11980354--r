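# run code under a temporary seed, restoring the caller's RNG state so that
# seeded internals (multistart jitter) never perturb user-level streams
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive independent child seeds from one master seed, one per named
# component, so toggling one simulation component leaves the others' draws
# unchanged
.child_seeds <- function(seed, components) {
  s <- .with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                   length(components)))
  stats::setNames(as.integer(s), components)
}
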