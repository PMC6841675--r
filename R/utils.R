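## Internal helpers.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
## afterwards so seeded generators never perturb an enclosing simulation.
withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv))
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv))
  }
  set.seed(as.integer(seed))
  force(code)
}

.degToRad <- function(deg) deg * pi / 180
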