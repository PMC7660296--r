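#' Membrane response model for the kick synthesizer
#'
#' Phenomenological model of how the testbed membrane surface moves in
#' response to a kick, used to generate synthetic sensor recordings. The
#' surface displacement at a point is the sum of
#' \itemize{
#'   \item a forced component: the wall-displacement trajectory smoothed by a
#'     raised-cosine kernel of width `forced_smoothing` (finite
#'     contact/compliance), scaled by `coupling_gain` and attenuated
#'     exponentially with surface distance from the impact point
#'     (`exp(-r / attenuation_length)`), and
#'   \item free ringing: a damped sinusoid at the measured damped natural
#'     frequency `f_nd` with envelope `exp(-t / ring_decay)`, launched at
#'     each velocity discontinuity of the drive (kick start, peak arrival,
#'     return start, return end), with amplitude proportional to the velocity
#'     step, scaled by `(wall_displacement / ring_ref_displacement)^
#'     ring_exponent` (deeper indentation couples the release more strongly
#'     into the fundamental mode), and attenuated by distance like the forced
#'     component.
#' }
#' `ring_decay` is the envelope time constant of the emulated free vibration
#' as observed on the rig (ridge persisting on the order of a second,
#' frequency repeatable to 0.1 Hz); it is deliberately distinct from the
#' single-mode viscous time constant of [time_constant()], which
#' underpredicts the observed ring duration (see the methods vignette).
#'
#' @param f_nd Damped natural frequency of the membrane (Hz), > 0.
#' @param ring_decay Ring envelope time constant (s), > 0.
#' @param attenuation_length Amplitude e-folding distance (m), > 0.
#' @param coupling_gain Dimensionless forced-coupling gain, > 0.
#' @param forced_smoothing Raised-cosine smoothing width (s), >= 0.
#' @param ring_amplitude Ring displacement amplitude (m) for a nominal-speed
#'   velocity step at the reference wall displacement and zero distance.
#' @param ring_ref_displacement Reference wall displacement (m).
#' @param ring_exponent Exponent of the displacement scaling, >= 0.
#' @param slow_mode_fraction Amplitude of the slow sway mode, as a fraction
#'   of the reference wall displacement when the kick is at the reference
#'   displacement; 0 disables it. The amplitude scales as
#'   `(wall_displacement / ring_ref_displacement)^slow_mode_exponent`. The sway is a damped
#'   low-frequency oscillation of the tensioned membrane excited when
#'   loading completes (peak arrival) and when unloading completes (return
#'   end); it reproduces the observed concentration of acoustic and
#'   piezoelectric signal power around 2 Hz.
#' @param slow_mode_freq Sway frequency (Hz), > 0.
#' @param slow_mode_decay Sway envelope time constant (s), > 0.
#' @param slow_mode_exponent Exponent of the sway displacement scaling.
#' @return An object of class `membrane_response_model`.
#' @export
membrane_response_model <- function(f_nd = 18.70,
                                    ring_decay = 0.30,
                                    attenuation_length = 0.202,
                                    coupling_gain = 1,
                                    forced_smoothing = 0.40,
                                    ring_amplitude = 1.4e-4,
                                    ring_ref_displacement = 10e-3,
                                    ring_exponent = 2,
                                    slow_mode_fraction = 0.30,
                                    slow_mode_freq = 2.25,
                                    slow_mode_decay = 0.40,
                                    slow_mode_exponent = 2) {
  v <- c(f_nd, ring_decay, attenuation_length, coupling_gain,
         ring_amplitude, ring_ref_displacement, slow_mode_freq,
         slow_mode_decay)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all membrane response model parameters must be positive")
  if (forced_smoothing < 0 || ring_exponent < 0 || slow_mode_fraction < 0 ||
      slow_mode_exponent < 0)
    stop("forced_smoothing, ring_exponent and slow_mode_fraction must be >= 0")
  structure(list(f_nd = f_nd, ring_decay = ring_decay,
                 attenuation_length = attenuation_length,
                 coupling_gain = coupling_gain,
                 forced_smoothing = forced_smoothing,
                 ring_amplitude = ring_amplitude,
                 ring_ref_displacement = ring_ref_displacement,
                 ring_exponent = ring_exponent,
                 slow_mode_fraction = slow_mode_fraction,
                 slow_mode_freq = slow_mode_freq,
                 slow_mode_decay = slow_mode_decay,
                 slow_mode_exponent = slow_mode_exponent),
            class = "membrane_response_model")
}

# Raised-cosine (Hann) smoothing kernel, unit sum.
smoothing_kernel <- function(width, Fs) {
  L <- max(1L, round(width * Fs))
  if (L <= 2L) return(1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  w / sum(w)
}

# Forced + ring surface motion components at one sensor point for one kick.
# Returns displacement, velocity and acceleration series on the grid `t`
# (seconds, absolute), for a kick whose drive starts at `t0`. The ring terms
# are evaluated in closed form so their onsets introduce no numerical
# differentiation spikes.
kick_motion_components <- function(profile, t, t0, distance, model, Fs) {
  wf <- actuator_waveform(profile, Fs)
  att <- model$coupling_gain * exp(-distance / model$attenuation_length)
  n <- length(t)
  disp <- vel <- acc <- numeric(n)

  # forced component: smoothed trapezoid placed at t0
  kern <- smoothing_kernel(model$forced_smoothing, Fs)
  xf <- stats::convolve(wf$x, rev(kern), type = "open")
  # centre the kernel delay: the smoothed onset begins `lag` samples before
  # the commanded kick start
  lag <- floor((length(kern) - 1) / 2)
  i0 <- which.min(abs(t - t0)) - lag
  if (i0 < 1L) {
    xf <- xf[(2L - i0):length(xf)]
    i0 <- 1L
  }
  idx <- i0:min(n, i0 + length(xf) - 1L)
  disp[idx] <- disp[idx] + att * xf[seq_along(idx)]
  vf <- num_deriv(disp, Fs)     # forced part only so far
  af <- num_deriv(vf, Fs)
  vel <- vel + vf
  acc <- acc + af

  # free ringing at each velocity discontinuity of the drive
  alpha <- 1 / model$ring_decay
  wd <- 2 * pi * model$f_nd
  scale <- (profile$wall_displacement / model$ring_ref_displacement)^
    model$ring_exponent
  ev <- wf$events
  # coincident events (zero pause) merge into a single step
  ev <- stats::aggregate(dv ~ time, data = ev, FUN = sum)
  for (j in seq_len(nrow(ev))) {
    tj <- t0 + ev$time[j]
    C <- -model$ring_amplitude * (ev$dv[j] / ACTUATOR_MAX_SPEED) * scale *
      exp(-distance / model$attenuation_length)
    tt <- t - tj
    on <- tt >= 0
    e <- exp(-alpha * tt[on])
    s <- sin(wd * tt[on]); cc <- cos(wd * tt[on])
    disp[on] <- disp[on] + C * e * s
    vel[on] <- vel[on] + C * e * (wd * cc - alpha * s)
    acc[on] <- acc[on] + C * e * ((alpha^2 - wd^2) * s - 2 * alpha * wd * cc)
  }

  # slow sway mode of the tensioned membrane: a damped low-frequency
  # oscillation (~2 Hz) excited when loading completes (peak arrival) and
  # when unloading completes (return end), amplitude proportional to the
  # wall displacement; closed-form derivatives
  if (model$slow_mode_fraction > 0) {
    As <- model$slow_mode_fraction * model$ring_ref_displacement *
      (profile$wall_displacement / model$ring_ref_displacement)^
        model$slow_mode_exponent *
      exp(-distance / model$attenuation_length) * model$coupling_gain
    ws <- 2 * pi * model$slow_mode_freq
    als <- 1 / model$slow_mode_decay
    t_rise <- profile$wall_displacement /
      (profile$actuator_speed * profile$speed_derating)
    launch <- c(t0 + t_rise, t0 + wf$duration)
    sgn <- c(1, -1)
    for (j in 1:2) {
      tt <- t - launch[j]
      on <- tt >= 0
      e <- exp(-als * tt[on])
      s <- sin(ws * tt[on]); cc <- cos(ws * tt[on])
      disp[on] <- disp[on] + sgn[j] * As * e * s
      vel[on] <- vel[on] + sgn[j] * As * e * (ws * cc - als * s)
      acc[on] <- acc[on] + sgn[j] * As * e *
        ((als^2 - ws^2) * s - 2 * als * ws * cc)
    }
  }
  list(disp = disp, vel = vel, acc = acc)
}

#' Membrane surface displacement in response to a kick
#'
#' Evaluates the membrane response model for a single kick: the surface
#' displacement time series at `sensor_point` for a kick applied at the
#' profile's impact point, starting at time 0.
#'
#' @param profile A [kick_profile()].
#' @param sensor_point Sensor position `c(x, y)` (m) in membrane-centred
#'   coordinates.
#' @param model A [membrane_response_model()].
#' @param Fs Sampling rate (Hz).
#' @param duration Length of the returned series (s); defaults to the kick
#'   duration plus five ring decay constants.
#' @param geometry Optional [flat_geometry()] against which both points are
#'   bounds-checked.
#' @return List with `t` (s) and `disp` (m).
#' @export
membrane_response <- function(profile, sensor_point, model, Fs = 2000,
                              duration = NULL, geometry = NULL) {
  stopifnot(inherits(profile, "kick_profile"),
            inherits(model, "membrane_response_model"))
  if (!is.null(geometry)) {
    check_on_membrane(profile$impact_point, geometry)
    check_on_membrane(sensor_point, geometry)
  }
  if (is.null(duration))
    duration <- kick_duration(profile) + 5 * model$ring_decay
  t <- seq(0, duration, by = 1 / Fs)
  r <- sqrt(sum((sensor_point - profile$impact_point)^2))
  cmp <- kick_motion_components(profile, t, 0, r, model, Fs)
  list(t = t, disp = cmp$disp)
}

check_on_membrane <- function(point, geometry) {
  stopifnot(inherits(geometry, "flat_geometry"))
  if (abs(point[1]) > geometry$side_a / 2 + 1e-12 ||
      abs(point[2]) > geometry$side_b / 2 + 1e-12)
    stop("point (", point[1], ", ", point[2],
         ") lies outside the membrane bounds")
  invisible(TRUE)
}
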