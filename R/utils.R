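# internal helpers shared across modules

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the current stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fan a root seed out into named per-stage seeds (all < 2^31).
deriveSeeds <- function(rootSeed, labels) {
  withSeed(rootSeed, setNames(sample.int(.Machine$integer.max - 1L,
                                         length(labels)), labels))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# local maxima of x with at least `minDist` samples separation, height > thr
localMaxima <- function(x, minDist, thr = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > thr]
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) >= minDist)) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}
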