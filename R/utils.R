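# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards, so seeded operations never perturb user RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range R requires.
childSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 7919) %% 2147483647)
}

stageFactor <- function(x) factor(as.character(x), levels = STAGES)

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}
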