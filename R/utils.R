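# Small internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# A self-contained RNG stream: draws do not disturb (and are not disturbed by)
# the global RNG state.  Used so that dataset generation and weight
# initialisation are pure functions of their seeds.
.seededRNG <- function(seed) {
  state <- NULL
  wrap <- function(f) {
    function(...) {
      had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
      old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
      if (is.null(state)) set.seed(seed)
      else assign(".Random.seed", state, envir = .GlobalEnv)
      res <- f(...)
      state <<- get(".Random.seed", envir = .GlobalEnv)
      if (had) assign(".Random.seed", old, envir = .GlobalEnv)
      else rm(".Random.seed", envir = .GlobalEnv)
      res
    }
  }
  list(rnorm = wrap(stats::rnorm), runif = wrap(stats::runif),
       sample = wrap(base::sample), rbinom = wrap(stats::rbinom))
}

.sigmoid <- function(x) stats::plogis(x)

# ceil-mode output length of a strided window op under "same" padding
.ceilDiv <- function(a, b) (a + b - 1L) %/% b

# Stable 32-bit hash of a character string (FNV-1a), for config fingerprints
# and per-component seed derivation; keeps derived seeds below 2^31.
.strHash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  as.integer(h)
}

# Derive a child seed from a base seed and a component tag.
.deriveSeed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + .strHash(tag)) %% 2147483647)
}
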