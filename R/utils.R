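# Run code under a temporary RNG state. When seed is NULL the current stream
# is used (and advanced); otherwise the global .Random.seed is restored on
# exit so seeded helpers do not perturb the caller's stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.isCount <- function(n) is.numeric(n) && length(n) == 1L && !is.na(n) &&
  n >= 1 && n == round(n)
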