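#' Spectral analysis configuration
#'
#' Hann-windowed segment settings shared by [welch_psd()] and
#' [spectrogram()]. The packaged defaults follow the characterization
#' settings: PSD with a 1 s Hann window and 50% overlap (1 Hz resolution);
#' spectrograms use 0.5 s windows with 80% overlap (2 Hz frequency step,
#' 100 ms hop).
#'
#' @param window Window type; only `"hann"` is supported.
#' @param window_length Window length (s), > 0.
#' @param overlap_fraction Fractional overlap between segments, in \[0, 1).
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(window = "hann", window_length = 1,
                            overlap_fraction = 0.5) {
  if (!identical(window, "hann")) stop("only the hann window is supported")
  if (!is.finite(window_length) || window_length <= 0)
    stop("window_length must be > 0")
  if (!is.finite(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  structure(list(window = window, window_length = window_length,
                 overlap_fraction = overlap_fraction),
            class = "spectral_config")
}

#' @rdname spectral_config
#' @export
spectrogram_config <- function(window_length = 0.5, overlap_fraction = 0.8)
  spectral_config("hann", window_length, overlap_fraction)

hann_window <- function(L) 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))

#' Welch power spectral density
#'
#' Averaged modified periodogram over overlapping Hann-windowed segments,
#' scaled as a one-sided density so that the PSD integrates to the signal
#' variance (Parseval). The frequency resolution is the reciprocal of the
#' window length.
#'
#' @param x Numeric series, at least one window long.
#' @param Fs Sampling rate (Hz).
#' @param cfg A [spectral_config()].
#' @param demean Subtract the series mean first (default `TRUE`).
#' @return List of class `psd` with `f` (Hz) and `p` (power density,
#'   units\eqn{^2}/Hz).
#' @export
welch_psd <- function(x, Fs, cfg = spectral_config(), demean = TRUE) {
  stopifnot(inherits(cfg, "spectral_config"))
  L <- round(cfg$window_length * Fs)
  if (length(x) < L)
    stop("record shorter than one spectral window (",
         cfg$window_length, " s)")
  if (demean) x <- x - mean(x)
  w <- hann_window(L)
  hop <- max(1L, round(L * (1 - cfg$overlap_fraction)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  acc <- numeric(L)
  for (s in starts) {
    X <- stats::fft(x[s:(s + L - 1L)] * w)
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * Fs * sum(w^2))
  half <- floor(L / 2) + 1L
  p <- p[1:half]
  # fold negative frequencies into the one-sided density
  if (L %% 2L == 0L) p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  else p[2:half] <- 2 * p[2:half]
  structure(list(f = (0:(half - 1L)) * Fs / L, p = p), class = "psd")
}

#' Short-time Fourier spectrogram
#'
#' Hann-windowed short-time spectra on the configured grid; with the default
#' [spectrogram_config()] at 2 kHz sampling this yields a 2 Hz frequency
#' step and a 100 ms hop.
#'
#' @param x Numeric series, at least one window long.
#' @param Fs Sampling rate (Hz).
#' @param cfg A [spectral_config()]; default [spectrogram_config()].
#' @return List of class `stft` with `t` (segment centres, s), `f` (Hz) and
#'   `magnitude` (matrix, frequencies x times).
#' @export
spectrogram <- function(x, Fs, cfg = spectrogram_config()) {
  stopifnot(inherits(cfg, "spectral_config"))
  L <- round(cfg$window_length * Fs)
  if (length(x) < L)
    stop("record shorter than one spectral window (",
         cfg$window_length, " s)")
  w <- hann_window(L)
  hop <- max(1L, round(L * (1 - cfg$overlap_fraction)))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  half <- floor(L / 2) + 1L
  mag <- matrix(0, nrow = half, ncol = length(starts))
  for (j in seq_along(starts)) {
    s <- starts[j]
    X <- stats::fft(x[s:(s + L - 1L)] * w)
    mag[, j] <- Mod(X[1:half])
  }
  structure(list(t = (starts - 1L + L / 2) / Fs,
                 f = (0:(half - 1L)) * Fs / L,
                 magnitude = mag),
            class = "stft")
}

#' Dominant frequency mode of a PSD
#'
#' Frequency of the maximum PSD value within the analysis band; exact ties
#' break toward the lower frequency.
#'
#' @param psd A `psd` from [welch_psd()] (or any list with `f` and `p`).
#' @param band Analysis band (Hz), default 1-40.
#' @return Dominant mode (Hz).
#' @export
dominant_mode <- function(psd, band = c(1, 40)) {
  if (is.null(psd$f) || is.null(psd$p) || length(psd$p) == 0L)
    stop("empty PSD")
  sel <- psd$f >= band[1] & psd$f <= band[2]
  if (!any(sel)) stop("no PSD bins inside the analysis band")
  f <- psd$f[sel]; p <- psd$p[sel]
  f[which.max(p)]  # which.max returns the first (lowest-frequency) maximum
}
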