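#' Per-sensor analysis series of a recording
#'
#' Maps recording channels to the series the characterization pipeline
#' works on: the acoustic and piezoelectric channels directly, and the
#' Euclidean magnitude of the three accelerometer axes (computed on the raw
#' axes, before any filtering, so the static 1 g offset linearizes the
#' magnitude in the vibration signal).
#'
#' @param rec A `sensor_recording`.
#' @return Named list of numeric series (`acoustic`, `piezoelectric`,
#'   `accelerometer` — whichever are present).
#' @export
sensor_series <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  ch <- rec$channels
  out <- list()
  if ("acoustic" %in% colnames(ch)) out$acoustic <- as.numeric(ch[, "acoustic"])
  if ("piezoelectric" %in% colnames(ch))
    out$piezoelectric <- as.numeric(ch[, "piezoelectric"])
  ax <- c("accelerometer_x", "accelerometer_y", "accelerometer_z")
  if (all(ax %in% colnames(ch)))
    out$accelerometer <- accel_magnitude(ch[, ax[1]], ch[, ax[2]], ch[, ax[3]])
  if (!length(out)) stop("recording has no recognized sensor channels")
  out
}

# Quiet-window start for the noise estimate: 6 s after the end of the
# previous kick when there is one; otherwise half a second into the
# pre-kick lead-in, ending half a second before the first kick.
auto_quiet_start <- function(rec, noise_window) {
  sch <- rec$schedule
  if (is.null(sch)) return(0)
  starts <- sch$entries$start_time
  first <- min(starts)
  if (first >= noise_window + 1) return(max(0.5, first - noise_window - 0.5))
  0
}

kick_intervals <- function(rec, post = 0.5) {
  sch <- rec$schedule
  if (is.null(sch)) stop("recording carries no schedule metadata")
  data.frame(
    start = sch$entries$start_time,
    end = mapply(function(s, p) s + kick_duration(p) + post,
                 sch$entries$start_time, sch$entries$profile))
}

#' Characterize every sensor of a recording
#'
#' The full pipeline: band-pass each sensor series (1-40 Hz, 4th-order
#' zero-phase Butterworth by default), estimate the noise floor over a quiet
#' window, partition at `h = m e`, and report energies, SNR and the dominant
#' Welch mode per sensor.
#'
#' @param rec A `sensor_recording`.
#' @param band Analysis passband (Hz).
#' @param m Threshold multiplier.
#' @param noise_window Quiet-window length (s).
#' @param quiet_start Quiet-window start (s); `NULL` picks it automatically
#'   from the schedule metadata (clear of any kick).
#' @param spectral A [spectral_config()] for the PSD.
#' @param filter_order Butterworth order of the conditioning band-pass.
#' @return data.frame with one row per sensor: `sensor`, `e`, `h`, `n_S`,
#'   `n_N`, `E_S`, `E_N`, `snr` (dB, `NA` when undefined), `dominant_mode`
#'   (Hz).
#' @export
analyze_recording <- function(rec, band = c(1, 40), m = 5, noise_window = 2,
                              quiet_start = NULL,
                              spectral = spectral_config(),
                              filter_order = 4L) {
  series <- sensor_series(rec)
  Fs <- rec$sampling_rate
  if (is.null(quiet_start)) quiet_start <- auto_quiet_start(rec, noise_window)
  spec <- filter_spec("bandpass", band, order = filter_order)
  rows <- lapply(names(series), function(nm) {
    V <- bandpass(series[[nm]], Fs, spec)
    mt <- kick_signal_metrics(V, Fs, m = m, noise_window = noise_window,
                              quiet_start = quiet_start, band = band,
                              spectral = spectral)
    data.frame(sensor = nm, e = mt$e, h = mt$h, n_S = mt$n_S, n_N = mt$n_N,
               E_S = mt$E_S, E_N = mt$E_N, snr = mt$snr,
               dominant_mode = mt$dominant_mode)
  })
  do.call(rbind, rows)
}

#' Dominant mode of the post-kick free vibration
#'
#' Extracts the ringing segment that follows a kick (from just before the
#' return-stroke end to `ring_window` seconds after it), band-passes it and
#' reports the dominant Welch mode — the pipeline's estimate of the damped
#' natural frequency of the membrane.
#'
#' @param rec A `sensor_recording` with schedule metadata.
#' @param sensor Sensor series to use (default `"accelerometer"`, the sensor
#'   most responsive to the free vibration).
#' @param kick Index of the kick in the schedule (default 1).
#' @param ring_window Segment length after the kick end (s); must cover at
#'   least one spectral window.
#' @param band,spectral,filter_order As in [analyze_recording()].
#' @return Dominant mode (Hz).
#' @export
ring_dominant_mode <- function(rec, sensor = "accelerometer", kick = 1L,
                               ring_window = 1.1, band = c(1, 40),
                               spectral = spectral_config(),
                               filter_order = 4L) {
  psd <- ring_psd(rec, sensor, kick, ring_window, band, spectral, filter_order)
  dominant_mode(psd, band)
}

#' @rdname ring_dominant_mode
#' @export
ring_psd <- function(rec, sensor = "accelerometer", kick = 1L,
                     ring_window = 1.1, band = c(1, 40),
                     spectral = spectral_config(), filter_order = 4L) {
  series <- sensor_series(rec)
  if (!sensor %in% names(series))
    stop("recording has no ", sensor, " series")
  Fs <- rec$sampling_rate
  sch <- rec$schedule
  if (is.null(sch)) stop("recording carries no schedule metadata")
  p <- sch$entries$profile[[kick]]
  t_end <- sch$entries$start_time[kick] + kick_duration(p)
  i0 <- max(1L, round((t_end - 0.05) * Fs))
  i1 <- min(length(series[[sensor]]), i0 + round(ring_window * Fs))
  V <- bandpass(series[[sensor]], Fs, filter_spec("bandpass", band,
                                                  order = filter_order))
  welch_psd(V[i0:i1], Fs, spectral)
}

#' Threshold-crossing kick detection
#'
#' A kick counts as detected when the band-passed response holds at least
#' one contiguous run of supra-threshold samples (`|V| > h`) of at least
#' `min_run` seconds inside the kick interval (kick start to return-stroke
#' end plus a free-vibration allowance).
#'
#' @param V Band-passed sensor series.
#' @param Fs Sampling rate (Hz).
#' @param h Threshold (signal units).
#' @param interval `c(start, end)` (s) of the kick interval.
#' @param min_run Minimum supra-threshold run length (s), default 0.010.
#' @return Logical.
#' @export
kick_detected <- function(V, Fs, h, interval, min_run = 0.010) {
  i0 <- max(1L, round(interval[1] * Fs))
  i1 <- min(length(V), round(interval[2] * Fs))
  if (i1 <= i0) return(FALSE)
  supra <- abs(V[i0:i1]) > h
  if (!any(supra)) return(FALSE)
  r <- rle(supra)
  max(r$lengths[r$values]) >= max(1L, round(min_run * Fs))
}
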