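## Internal utilities: derived seed streams and scoped RNG use.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a deterministic 31-bit seed from a root seed and a path of small
## integers (stage, subject, repeat, ...). LCG-style mixing keeps streams for
## different paths distinct without storing RNG state.
deriveSeed <- function(seed, ...) {
  ks <- c(...)
  x <- as.double(seed %% 2147483647)
  for (k in ks) {
    x <- (x * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(x)
}

## Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so package functions never perturb the user's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Stop with a consistent message prefix.
abort <- function(...) stop(..., call. = FALSE)

assertScalarNumber <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    abort(name, " must be a single finite number")
  if (positive && x <= 0) abort(name, " must be positive")
  invisible(x)
}
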