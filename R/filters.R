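#' Butterworth filter specification
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param band Corner frequencies (Hz): `c(lo, hi)` for bandpass, a single
#'   cut-off for lowpass.
#' @param order Butterworth order (default 4, the order used throughout the
#'   conditioning pipeline); must be even when `zero_phase` for symmetric
#'   roll-off.
#' @param zero_phase Apply the filter forward and backward (default `TRUE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), band,
                        order = 4L, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
      stop("bandpass band must be c(lo, hi) with 0 < lo < hi")
  } else if (length(band) != 1L || band <= 0) {
    stop("lowpass band must be a single positive cut-off")
  }
  if (order < 1L || (zero_phase && order %% 2L != 0L))
    stop("order must be a positive integer, even when zero_phase")
  structure(list(kind = kind, band = as.numeric(band),
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Forward-backward filtering with odd (reflective) end padding: avoids the
# edge transients of plain forward-backward filtering on short kick records.
zero_phase_filter <- function(x, flt, pad = NULL) {
  n <- length(x)
  if (n < 4L) return(x)
  p <- if (is.null(pad)) min(n - 1L, 1000L) else min(n - 1L, pad)
  xe <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  yf <- signal::filter(flt, xe)
  yb <- rev(signal::filter(flt, rev(yf)))
  as.numeric(yb[(p + 1):(p + n)])
}

butter_from_spec <- function(spec, Fs) {
  ny <- Fs / 2
  if (spec$band[length(spec$band)] >= ny)
    stop("filter band must lie inside (0, Fs/2)")
  if (spec$kind == "bandpass")
    signal::butter(spec$order, spec$band / ny, type = "pass")
  else
    signal::butter(spec$order, spec$band / ny, type = "low")
}

#' Band-pass (or low-pass) filter a series
#'
#' Applies the Butterworth filter described by `spec`; with
#' `zero_phase = TRUE` the filter runs forward and backward over a
#' reflectively padded copy, so the output has zero phase shift and the same
#' length as the input. The default specification is the conditioning filter
#' used on all sensor channels: 4th-order Butterworth, 1-40 Hz passband,
#' zero phase.
#'
#' @param x Numeric series.
#' @param Fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered series, same length as `x`.
#' @export
bandpass <- function(x, Fs, spec = filter_spec("bandpass", c(1, 40))) {
  stopifnot(inherits(spec, "filter_spec"))
  flt <- butter_from_spec(spec, Fs)
  pad <- NULL
  if (spec$kind == "bandpass") {
    # a static offset lies far outside the passband but excites a slow edge
    # transient through the low corner; remove it and pad generously
    x <- x - mean(x)
    pad <- round(2 * Fs / spec$band[1])
  }
  if (spec$zero_phase) zero_phase_filter(x, flt, pad = pad)
  else as.numeric(signal::filter(flt, x))
}

#' Condition a raw force-sensor signal
#'
#' Reproduces the force-channel conditioning of the data-acquisition chain:
#' 4th-order zero-phase Butterworth low-pass at 50 Hz, affine
#' voltage-to-force calibration, and subtraction of the offset caused by the
#' initial compression of the sensor in its holder.
#'
#' @param raw Raw sensor series (V).
#' @param Fs Sampling rate (Hz).
#' @param calibration Affine map `c(intercept, slope)` (N, N/V) or a
#'   function of the voltage.
#' @param offset Offset force to subtract (N).
#' @param cutoff Low-pass cut-off (Hz), default 50.
#' @return Conditioned force series (N).
#' @export
condition_force_signal <- function(raw, Fs, calibration = c(0, 1), offset = 0,
                                   cutoff = 50) {
  filtered <- bandpass(raw, Fs, filter_spec("lowpass", cutoff))
  f <- if (is.function(calibration)) {
    calibration(filtered)
  } else {
    if (length(calibration) != 2L || !all(is.finite(calibration)))
      stop("calibration must be c(intercept, slope) or a function")
    calibration[1] + calibration[2] * filtered
  }
  f - offset
}
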