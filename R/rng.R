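# Local RNG streams. Every stochastic operation in the package takes an
# explicit seed and draws from its own stream, leaving the caller's
# .Random.seed untouched.

new_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  e$state <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  e
}

rng_eval <- function(rng, f) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  v <- f()
  rng$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  v
}

rng_norm <- function(rng, n, mean = 0, sd = 1) {
  rng_eval(rng, function() rnorm(n, mean, sd))
}

rng_unif <- function(rng, n, min = 0, max = 1) {
  rng_eval(rng, function() runif(n, min, max))
}

# a seeded permutation of 1..n
rng_sample <- function(rng, n, size = n, replace = FALSE) {
  rng_eval(rng, function() sample.int(n, size, replace = replace))
}

# one uniform integer in 1..k
rng_int <- function(rng, k) {
  rng_eval(rng, function() sample.int(k, 1L))
}
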