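# Run expr under a fixed RNG seed, restoring the caller's RNG state so that
# synthesis is pure given (inputs, seed) without side effects on the session.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# First and second time derivatives of a uniformly sampled smooth series,
# central differences with one-sided ends.
num_deriv <- function(x, Fs) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * (Fs / 2)
  d[1] <- (x[2] - x[1]) * Fs
  d[n] <- (x[n] - x[n - 1]) * Fs
  d
}
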