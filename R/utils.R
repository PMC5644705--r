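`%||%` <- function(a, b) if (is.null(a)) b else a

## Seed handling: set the RNG for the duration of a call without clobbering
## the caller's stream when no seed is requested.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive k reproducible sub-seeds from one master seed (or NULLs when
## unseeded), so independent pipeline stages get independent streams and
## adding replications to one stage does not perturb another.
fork_seeds <- function(seed, k) {
  if (is.null(seed)) return(vector("list", k))
  with_seed(seed, as.list(sample.int(.Machine$integer.max, k)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
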