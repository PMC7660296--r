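# Shared fixtures, built in code.

# Dragon Skin 10 NV testbed membrane, 30-week prestress (side 178 mm).
testbed30 <- function() testbed_membrane(30)

# Noise-free copies of the packaged sensor set.
noiseless_sensors <- function() {
  lapply(default_sensor_models(), function(m) {
    m$noise_floor_rms <- 0
    m
  })
}

# Brute-force reimplementation of the threshold/energy/SNR chain with plain
# loops, independent of the package's vectorized path.
brute_force_metrics <- function(V, Fs, w, quiet_start, m) {
  i0 <- round(quiet_start * Fs) + 1L
  n_w <- round(w * Fs)
  acc <- 0
  for (i in i0:(i0 + n_w - 1L)) acc <- acc + abs(V[i])
  e <- acc / n_w
  h <- m * e
  S <- integer(); N <- integer()
  for (i in seq_along(V)) {
    if (abs(V[i]) > h) S <- c(S, i) else N <- c(N, i)
  }
  E_S <- 0; for (i in S) E_S <- E_S + V[i]^2
  E_N <- 0; for (i in N) E_N <- E_N + V[i]^2
  snr <- 10 * log10((E_S / length(S) - E_N / length(N)) / (E_N / length(N)))
  list(e = e, h = h, S = S, N = N, E_S = E_S, E_N = E_N, snr = snr)
}
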