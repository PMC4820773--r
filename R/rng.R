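# Seed plumbing: every stochastic operation takes an explicit integer seed
# and leaves the caller's RNG stream untouched.

with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# A resumable private RNG stream: each call continues where the last left
# off, without touching the caller's stream.
local_rng <- function(seed) {
  state <- NULL
  run <- function(fn) {
    old <- get0(".Random.seed", envir = globalenv())
    if (is.null(state)) set.seed(seed) else {
      assign(".Random.seed", state, envir = globalenv())
    }
    res <- fn()
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    res
  }
  list(
    sample_int = function(n) run(function() sample.int(n, 1L)),
    runif = function(n) run(function() stats::runif(n))
  )
}
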