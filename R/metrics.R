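#' Euclidean magnitude of 3-axis acceleration
#'
#' Per-sample \eqn{A = \sqrt{A_x^2 + A_y^2 + A_z^2}}. Applied to the raw
#' axis channels (which carry the 1 g static offset on the signal axis), the
#' magnitude is orientation-invariant and locally linear in the vibration
#' signal; the subsequent band-pass removes the static offset.
#'
#' @param ax,ay,az Axis series of equal length.
#' @return Magnitude series.
#' @export
accel_magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axis series must have equal lengths")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Noise floor estimate from a quiet window
#'
#' Mean absolute sensor response over a window of length `w` during which no
#' kick action is going on: \eqn{e = \frac{1}{F_s w}\sum |V_i|}. The window
#' should start well clear of the previous kick (6 s is used by the
#' automated pipeline) so the free vibration has fully decayed.
#'
#' @param V Sensor series.
#' @param Fs Sampling rate (Hz).
#' @param w Window length (s), default 2.
#' @param quiet_start Window start time (s), default 0.
#' @return Noise estimate `e` in signal units.
#' @export
noise_floor <- function(V, Fs, w = 2, quiet_start = 0) {
  i0 <- round(quiet_start * Fs) + 1L
  i1 <- i0 + round(w * Fs) - 1L
  if (i0 < 1L || i1 > length(V))
    stop("quiet window [", quiet_start, ", ", quiet_start + w,
         "] s lies outside the record")
  mean(abs(V[i0:i1]))
}

#' Threshold partition of a sensor response
#'
#' Splits the samples into signal `S` (samples with `|V| > h`, where
#' `h = m e`) and noise `N` (samples with `|V| <= h`); a sample exactly at
#' the threshold counts as noise. `S` and `N` always partition the record.
#'
#' @param V Sensor series.
#' @param e Noise estimate from [noise_floor()], >= 0.
#' @param m Threshold multiplier, > 0; default 5, the value found to give
#'   the most suitable threshold across datasets.
#' @return List with integer index vectors `S` and `N` and the threshold `h`.
#' @export
threshold_partition <- function(V, e, m = 5) {
  if (!is.finite(e) || e < 0) stop("e must be >= 0")
  if (!is.finite(m) || m <= 0) stop("m must be > 0")
  h <- m * e
  S <- which(abs(V) > h)
  list(S = S, N = setdiff(seq_along(V), S), h = h)
}

#' Signal energy
#'
#' Sum of squared magnitudes over a sample set; an empty set has zero
#' energy.
#'
#' @param x Numeric samples (a subset of a sensor series).
#' @return Energy in squared signal units.
#' @export
signal_energy <- function(x) {
  if (length(x) == 0L) return(0)
  sum(abs(x)^2)
}

#' Signal-to-noise ratio in decibels
#'
#' \eqn{SNR = 10\log_{10}((E_S/n_S - E_N/n_N)/(E_N/n_N))}: the noise power
#' is assumed constant throughout the response and subtracted from the
#' signal power before forming the ratio. When the mean signal power does
#' not exceed the mean noise power the SNR is undefined; an error of class
#' `fmsim_snr_undefined` is signalled, or `NA` returned with
#' `undefined = "na"`.
#'
#' @param E_S,E_N Signal and noise energies.
#' @param n_S,n_N Signal and noise sample counts; both must be positive.
#' @param undefined `"error"` (default) or `"na"`.
#' @return SNR (dB).
#' @export
snr_db <- function(E_S, n_S, E_N, n_N, undefined = c("error", "na")) {
  undefined <- match.arg(undefined)
  if (n_S <= 0) stop("no detected signal samples (n_S = 0)", call. = FALSE)
  if (n_N <= 0 || E_N <= 0) stop("noise energy must be positive", call. = FALSE)
  ps <- E_S / n_S; pn <- E_N / n_N
  if (ps <= pn) {
    if (undefined == "na") return(NA_real_)
    stop(structure(class = c("fmsim_snr_undefined", "error", "condition"),
                   list(message = "signal power below noise floor: SNR undefined",
                        call = sys.call(-1))))
  }
  10 * log10((ps - pn) / pn)
}

#' Kick signal metrics of one sensor response
#'
#' Runs the characterization chain on a conditioned (band-passed) sensor
#' series: noise-floor estimate over a quiet window, threshold partition at
#' `h = m e`, signal and noise energies and counts, SNR, and the dominant
#' frequency mode of the Welch PSD within the analysis band.
#'
#' @param V Conditioned sensor series.
#' @param Fs Sampling rate (Hz).
#' @param m Threshold multiplier (default 5).
#' @param noise_window Quiet-window length (s), default 2.
#' @param quiet_start Quiet-window start (s), default 0.
#' @param band Analysis band (Hz) for the dominant mode, default `c(1, 40)`.
#' @param spectral A [spectral_config()] for the Welch PSD.
#' @return An object of class `kick_signal_metrics`: list with `e`, `m`,
#'   `h`, `S`, `N`, `E_S`, `E_N`, `n_S`, `n_N`, `snr` (NA when undefined)
#'   and `dominant_mode` (Hz).
#' @export
kick_signal_metrics <- function(V, Fs, m = 5, noise_window = 2,
                                quiet_start = 0, band = c(1, 40),
                                spectral = spectral_config()) {
  e <- noise_floor(V, Fs, noise_window, quiet_start)
  part <- threshold_partition(V, e, m)
  E_S <- signal_energy(V[part$S])
  E_N <- signal_energy(V[part$N])
  n_S <- length(part$S); n_N <- length(part$N)
  snr <- if (n_S > 0L && E_N > 0)
    snr_db(E_S, n_S, E_N, n_N, undefined = "na") else NA_real_
  psd <- welch_psd(V, Fs, spectral)
  structure(list(e = e, m = m, h = part$h, S = part$S, N = part$N,
                 E_S = E_S, E_N = E_N, n_S = n_S, n_N = n_N,
                 snr = snr, dominant_mode = dominant_mode(psd, band)),
            class = "kick_signal_metrics")
}

#' @export
print.kick_signal_metrics <- function(x, ...) {
  cat(sprintf(paste0("<kick_signal_metrics> e = %.3g, h = %.3g, n_S = %d, ",
                     "SNR = %s dB, dominant mode = %g Hz\n"),
              x$e, x$h, x$n_S,
              if (is.na(x$snr)) "undefined" else sprintf("%.2f", x$snr),
              x$dominant_mode))
  invisible(x)
}
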