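## internal helpers

## Evaluate expr under a temporary RNG seed, restoring the caller's stream.
localSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Deterministically derive a 32-bit sub-seed from a master seed plus context
## integers (repetition, fold, ...). Arithmetic kept exact in doubles.
deriveSeed <- function(seed, ...) {
  x <- as.double(seed) %% 2147483647
  for (e in c(...)) {
    x <- (x * 69069 + as.double(e) * 12345 + 1) %% 2147483647
  }
  as.integer(x)
}

## Balanced random fold assignment: n subjects into `folds` folds.
foldAssignment <- function(n, folds, seed) {
  localSeed(seed, sample(rep_len(seq_len(folds), n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
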