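#' Vibration sensor model
#'
#' Qualitative emulation of one of the candidate wearable sensors. The
#' transfer behaviours mirror the observed responses of the hardware:
#' \describe{
#'   \item{acoustic}{sealed-chamber microphone; output proportional to the
#'     membrane surface displacement over a flat 1-100 Hz passband.}
#'   \item{piezoelectric}{brass-backed piezoceramic diaphragm; output
#'     proportional to the surface displacement rate, low-passed at 10 Hz
#'     (its observed power is concentrated below 10 Hz).}
#'   \item{accelerometer}{3-axis MEMS device; output is the surface
#'     acceleration projected on one axis (plus the 1 g static offset),
#'     band-limited by a first-order 50 Hz RC response, with independent
#'     noise on all three axes.}
#' }
#'
#' @param kind `"acoustic"`, `"piezoelectric"` or `"accelerometer"`.
#' @param passband Nominal passband `c(lo, hi)` (Hz); must sit below the
#'   Nyquist frequency of any recording the sensor is used in.
#' @param sensitivity Output volts per input unit (m, m/s or m/s\eqn{^2}).
#' @param noise_floor_rms Gaussian noise RMS (V) per channel, >= 0.
#' @param lowpass Low-pass corner (Hz) applied to the displacement rate
#'   (piezoelectric), or `NA`.
#' @param lowpass_order Butterworth order of that low-pass.
#' @param bandwidth First-order RC bandwidth limit (Hz, accelerometer), or
#'   `NA`.
#' @param gravity_offset Include the 1 g static offset on the signal axis
#'   (accelerometer).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(kind = c("acoustic", "piezoelectric", "accelerometer"),
                         passband = c(1, 100),
                         sensitivity = 1,
                         noise_floor_rms = 0,
                         lowpass = NA_real_,
                         lowpass_order = 4L,
                         bandwidth = NA_real_,
                         gravity_offset = FALSE) {
  kind <- match.arg(kind)
  if (length(passband) != 2L || passband[1] <= 0 || passband[2] <= passband[1])
    stop("passband must be c(lo, hi) with 0 < lo < hi")
  if (!is.finite(sensitivity) || sensitivity <= 0)
    stop("sensitivity must be > 0")
  if (!is.finite(noise_floor_rms) || noise_floor_rms < 0)
    stop("noise_floor_rms must be >= 0")
  structure(list(kind = kind, passband = as.numeric(passband),
                 sensitivity = sensitivity,
                 noise_floor_rms = noise_floor_rms,
                 lowpass = lowpass, lowpass_order = as.integer(lowpass_order),
                 bandwidth = bandwidth,
                 gravity_offset = isTRUE(gravity_offset)),
            class = "sensor_model")
}

GRAVITY <- 9.81  # m/s^2

sensor_channel_names <- function(sensor) {
  switch(sensor$kind,
         acoustic = "acoustic",
         piezoelectric = "piezoelectric",
         accelerometer = c("accelerometer_x", "accelerometer_y",
                           "accelerometer_z"))
}

# Noise-free sensor output channels (volts) from membrane motion components.
sensor_transform <- function(sensor, cmp, Fs) {
  switch(sensor$kind,
    acoustic = {
      matrix(sensor$sensitivity * cmp$disp, ncol = 1,
             dimnames = list(NULL, "acoustic"))
    },
    piezoelectric = {
      v <- cmp$vel
      if (is.finite(sensor$lowpass)) {
        lp <- signal::butter(sensor$lowpass_order,
                             sensor$lowpass / (Fs / 2), type = "low")
        v <- zero_phase_filter(v, lp)
      }
      matrix(sensor$sensitivity * v, ncol = 1,
             dimnames = list(NULL, "piezoelectric"))
    },
    accelerometer = {
      a <- cmp$acc
      if (is.finite(sensor$bandwidth)) {
        rc <- signal::butter(1, sensor$bandwidth / (Fs / 2), type = "low")
        a <- zero_phase_filter(a, rc)
      }
      g0 <- if (sensor$gravity_offset) GRAVITY else 0
      n <- length(a)
      m <- cbind(accelerometer_x = numeric(n),
                 accelerometer_y = numeric(n),
                 accelerometer_z = sensor$sensitivity * (a + g0))
      m
    })
}

#' Synthesize a multi-sensor recording of a kick schedule
#'
#' The virtual rig: evaluates the membrane response model for every kick in
#' the schedule at every sensor position, applies each sensor's transfer
#' behaviour and sensitivity, and adds Gaussian noise at the sensor's noise
#' floor. The result is bit-identical for identical inputs and seed.
#'
#' @param schedule A [kick_schedule()].
#' @param sensors List of placed sensors, each `list(model = sensor_model,
#'   position = c(x, y))`; positions in membrane-centred metres.
#' @param membrane A [membrane_response_model()]; packaged default from
#'   [default_membrane_model()].
#' @param geometry A [flat_geometry()] for bounds checks; default the
#'   30-week stretched testbed.
#' @param Fs Sampling rate (Hz), default 2000.
#' @param duration Recording length (s); default runs from 0 to the last kick
#'   end plus 2.5 s.
#' @param seed Integer seed for the sensor noise.
#' @return An object of class `sensor_recording`: list with `sampling_rate`,
#'   `t`, `channels` (numeric matrix, one column per channel), `sensors`
#'   (placement metadata), `schedule`, `seed`.
#' @export
synthesize_recording <- function(schedule, sensors,
                                 membrane = default_membrane_model(),
                                 geometry = testbed_membrane(30)$geometry,
                                 Fs = 2000, duration = NULL, seed = 1L) {
  stopifnot(inherits(schedule, "kick_schedule"),
            inherits(membrane, "membrane_response_model"))
  if (length(sensors) == 0L) stop("at least one placed sensor is required")
  for (s in sensors) {
    if (!inherits(s$model, "sensor_model"))
      stop("each sensor entry needs a sensor_model in $model")
    if (s$model$passband[2] >= Fs / 2)
      stop("sensor passband top must lie below the Nyquist frequency")
    check_on_membrane(s$position, geometry)
  }
  for (p in schedule$entries$profile)
    check_on_membrane(p$impact_point, geometry)
  if (is.null(duration)) duration <- schedule_end(schedule) + 2.5
  t <- seq(0, duration, by = 1 / Fs)
  n <- length(t)

  cols <- list()
  for (s in sensors) {
    cmp <- list(disp = numeric(n), vel = numeric(n), acc = numeric(n))
    for (i in seq_len(nrow(schedule$entries))) {
      p <- schedule$entries$profile[[i]]
      r <- sqrt(sum((s$position - p$impact_point)^2))
      ki <- kick_motion_components(p, t, schedule$entries$start_time[i],
                                   r, membrane, Fs)
      cmp$disp <- cmp$disp + ki$disp
      cmp$vel <- cmp$vel + ki$vel
      cmp$acc <- cmp$acc + ki$acc
    }
    cols[[length(cols) + 1L]] <- sensor_transform(s$model, cmp, Fs)
  }
  channels <- do.call(cbind, cols)
  # additive sensor noise, deterministic in the seed
  sds <- unlist(lapply(sensors, function(s)
    rep(s$model$noise_floor_rms, length(sensor_channel_names(s$model)))))
  noise <- with_seed(seed,
    matrix(stats::rnorm(n * ncol(channels)), nrow = n) %*% diag(sds, ncol(channels)))
  channels <- channels + noise
  structure(list(sampling_rate = Fs, t = t, channels = channels,
                 sensors = lapply(sensors, function(s)
                   list(kind = s$model$kind, position = s$position,
                        model = s$model)),
                 schedule = schedule, seed = as.integer(seed)),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %.1f s @ %g Hz, channels: %s\n",
              max(x$t), x$sampling_rate,
              paste(colnames(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write a recording as delimited text
#'
#' Header lines (prefixed `#`) carry the sampling rate, channel names, seed
#' and a digest of the kick schedule; one row per sample follows,
#' tab-delimited fixed decimal.
#'
#' @param rec A `sensor_recording`.
#' @param path Output file path.
#' @param digits Significant digits per sample.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 9L) {
  stopifnot(inherits(rec, "sensor_recording"))
  ent <- rec$schedule$entries
  digest <- paste(sprintf("%g:%d:%g", ent$start_time, ent$actuator_id,
                          vapply(ent$profile, `[[`, 0, "wall_displacement")),
                  collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate),
    sprintf("# channels: %s", paste(colnames(rec$channels), collapse = "\t")),
    sprintf("# seed: %d", rec$seed),
    sprintf("# schedule: %s", digest)), con)
  utils::write.table(signif(rec$channels, digits), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Recording file path.
#' @return A `sensor_recording` (placement and schedule metadata reduced to
#'   what the header carries).
#' @export
read_recording <- function(path) {
  all_lines <- readLines(path)
  hdr <- all_lines[startsWith(all_lines, "#")]
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(m)) stop("recording header missing field: ", key)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  Fs <- as.numeric(get_field("sampling_rate_hz"))
  chn <- strsplit(get_field("channels"), "\t", fixed = TRUE)[[1]]
  seed <- as.integer(get_field("seed"))
  dat <- utils::read.table(text = all_lines[!startsWith(all_lines, "#")],
                           sep = "\t", col.names = chn)
  ch <- as.matrix(dat)
  colnames(ch) <- chn
  structure(list(sampling_rate = Fs,
                 t = seq(0, by = 1 / Fs, length.out = nrow(ch)),
                 channels = ch, sensors = NULL,
                 schedule_digest = get_field("schedule"),
                 seed = seed),
            class = "sensor_recording")
}
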