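# Actuator characteristics of the kicking mechanism (linear servo actuators,
# 5 V supply): no-load speed and stroke, and the repeatability floor that
# sets the smallest reliable wall displacement.
#' @export
ACTUATOR_MAX_SPEED <- 12.43e-3   # m/s, no-load
#' @export
ACTUATOR_MAX_STROKE <- 146e-3    # m
#' @export
MIN_WALL_DISPLACEMENT <- 0.5e-3  # m, from the 0.4 mm actuator repeatability

#' Simulated fetal kick profile
#'
#' One simulated kick: the actuator pushes the membrane inward by
#' `wall_displacement` at `actuator_speed`, optionally holds at the peak,
#' then returns, i.e. a trapezoidal wall-displacement trajectory of total
#' duration `2 d / v + pause`.
#'
#' @param wall_displacement Peak wall displacement (m); must be at least
#'   [MIN_WALL_DISPLACEMENT] (actuator repeatability floor) and at most the
#'   membrane-safe maximum of 30 mm.
#' @param actuator_speed Actuator speed (m/s), in (0, [ACTUATOR_MAX_SPEED]].
#' @param pause_at_peak Hold time at peak displacement (s), >= 0.
#' @param probe Kicking probe: `"cylindrical_10mm"` (20-week fetal foot) or
#'   `"hemispherical_30mm"` (30-week fetal foot).
#' @param impact_point Impact point `c(x, y)` (m) in membrane-centred
#'   coordinates.
#' @param angle Angular orientation of the actuator (degrees): 90, 60 or 55.
#' @param speed_derating Multiplier in (0, 1\] applied to the actuator speed
#'   to emulate loaded-actuator slowdown; the default 1 uses the no-load
#'   speed.
#' @return An object of class `kick_profile`.
#' @export
kick_profile <- function(wall_displacement,
                         actuator_speed = ACTUATOR_MAX_SPEED,
                         pause_at_peak = 0,
                         probe = c("hemispherical_30mm", "cylindrical_10mm"),
                         impact_point = c(0, 0),
                         angle = 90,
                         speed_derating = 1) {
  probe <- match.arg(probe)
  if (!is.finite(wall_displacement) ||
      wall_displacement < MIN_WALL_DISPLACEMENT - 1e-12)
    stop("wall_displacement below the ", MIN_WALL_DISPLACEMENT * 1e3,
         " mm actuator repeatability floor")
  if (wall_displacement > 30e-3)
    stop("wall_displacement exceeds the membrane-safe maximum (30 mm)")
  if (!is.finite(actuator_speed) || actuator_speed <= 0 ||
      actuator_speed > ACTUATOR_MAX_SPEED + 1e-12)
    stop("actuator_speed must be in (0, ", ACTUATOR_MAX_SPEED * 1e3, "] mm/s")
  if (!is.finite(pause_at_peak) || pause_at_peak < 0)
    stop("pause_at_peak must be >= 0")
  if (!angle %in% c(90, 60, 55)) stop("angle must be one of 90, 60, 55")
  if (length(impact_point) != 2L || any(!is.finite(impact_point)))
    stop("impact_point must be c(x, y)")
  if (!is.finite(speed_derating) || speed_derating <= 0 || speed_derating > 1)
    stop("speed_derating must be in (0, 1]")
  structure(list(wall_displacement = wall_displacement,
                 actuator_speed = actuator_speed,
                 pause_at_peak = pause_at_peak,
                 probe = probe,
                 impact_point = as.numeric(impact_point),
                 angle = angle,
                 speed_derating = speed_derating),
            class = "kick_profile")
}

#' Duration of a kick profile
#'
#' Total trapezoid duration `2 d / v + pause` at the (derated) actuator
#' speed.
#'
#' @param profile A [kick_profile()].
#' @return Duration (s).
#' @export
kick_duration <- function(profile) {
  stopifnot(inherits(profile, "kick_profile"))
  v <- profile$actuator_speed * profile$speed_derating
  2 * profile$wall_displacement / v + profile$pause_at_peak
}

#' Commanded actuator trajectory of one kick
#'
#' Samples the trapezoidal wall-displacement trajectory at the impact point:
#' linear rise at the actuator speed to the peak displacement, hold, linear
#' return. Also reports the velocity discontinuities (time, velocity step) at
#' the trapezoid corners, which launch the membrane free vibration.
#'
#' @param profile A [kick_profile()].
#' @param Fs Sampling rate (Hz), > 0.
#' @return List with `t` (s), `x` (m), `events` (data.frame `time`, `dv`) and
#'   `duration` (s).
#' @export
actuator_waveform <- function(profile, Fs) {
  stopifnot(inherits(profile, "kick_profile"))
  if (!is.finite(Fs) || Fs <= 0) stop("Fs must be > 0")
  d <- profile$wall_displacement
  v <- profile$actuator_speed * profile$speed_derating
  p <- profile$pause_at_peak
  t_rise <- d / v
  dur <- 2 * t_rise + p
  t <- seq(0, dur, by = 1 / Fs)
  x <- pmax(0, v * pmin(t, t_rise) - v * pmax(t - t_rise - p, 0))
  events <- data.frame(
    time = c(0, t_rise, t_rise + p, dur),
    dv = c(v, -v, -v, v))
  list(t = t, x = x, events = events, duration = dur)
}

# Mean kick reaction force calibration knots (N) per probe, measured on the
# rig at 10 and 15 mm wall displacement, averaged over 40 membrane locations.
reaction_force_knots <- list(
  cylindrical_10mm  = list(d = c(10e-3, 15e-3), F = c(14.84, 33.15)),
  hemispherical_30mm = list(d = c(10e-3, 15e-3), F = c(26.01, 44.20)))

#' Kick reaction force from the membrane
#'
#' Piecewise-linear interpolation of the calibrated mean reaction force over
#' the per-probe knots, linearly extrapolated outside the measured range and
#' floored at zero.
#'
#' @param profile A [kick_profile()], or a probe name with `displacement`
#'   given.
#' @param displacement Optional wall displacement (m) overriding the
#'   profile's.
#' @return Reaction force (N).
#' @export
reaction_force <- function(profile, displacement = NULL) {
  if (inherits(profile, "kick_profile")) {
    probe <- profile$probe
    d <- if (is.null(displacement)) profile$wall_displacement else displacement
  } else {
    probe <- match.arg(profile, names(reaction_force_knots))
    if (is.null(displacement)) stop("displacement required with a probe name")
    d <- displacement
  }
  kn <- reaction_force_knots[[probe]]
  slope <- diff(kn$F) / diff(kn$d)
  pmax(0, kn$F[1] + slope * (d - kn$d[1]))
}

#' Timed multi-actuator kick schedule
#'
#' @param entries data.frame with columns `start_time` (s), `actuator_id`
#'   (1 or 2) and a list-column `profile` of [kick_profile()] objects.
#'   Entries are sorted by start time.
#' @param mode Kick mode the schedule was built under.
#' @return An object of class `kick_schedule`.
#' @export
kick_schedule <- function(entries,
                          mode = c("single", "dual_simultaneous",
                                   "dual_consecutive", "dual_random")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(entries),
            all(c("start_time", "actuator_id", "profile") %in% names(entries)))
  if (!all(entries$actuator_id %in% c(1L, 2L)))
    stop("actuator_id must be 1 or 2")
  if (!all(vapply(entries$profile, inherits, TRUE, "kick_profile")))
    stop("profile column must hold kick_profile objects")
  entries <- entries[order(entries$start_time), , drop = FALSE]
  rownames(entries) <- NULL
  if (mode == "dual_simultaneous") {
    n1 <- sum(entries$actuator_id == 1L)
    n2 <- sum(entries$actuator_id == 2L)
    if (n1 != n2)
      stop("dual_simultaneous requires equal kick counts per actuator")
  }
  structure(list(entries = entries, mode = mode), class = "kick_schedule")
}

#' Build a kick schedule from a kick mode
#'
#' Implements the simulator's kick modes: `single` runs one actuator with a
#' fixed inter-kick gap; `dual_simultaneous` pairs the two actuators at
#' identical start times (equal kick counts required); `dual_consecutive`
#' strictly alternates the actuators without overlap; `dual_random` draws
#' start times uniformly over the session.
#'
#' @param mode Kick mode.
#' @param profiles_1 List of [kick_profile()]s for actuator 1.
#' @param profiles_2 List of [kick_profile()]s for actuator 2 (dual modes).
#' @param gap Inter-kick gap (s) between the end of one kick and the start of
#'   the next (default 10 s, long enough for complete free-vibration decay).
#' @param session Session length (s) over which `dual_random` draws start
#'   times.
#' @param seed Integer seed for `dual_random`.
#' @param start_offset Start time (s) of the first kick.
#' @return A [kick_schedule()].
#' @export
schedule_from_mode <- function(mode = c("single", "dual_simultaneous",
                                        "dual_consecutive", "dual_random"),
                               profiles_1, profiles_2 = list(),
                               gap = 10, session = 60, seed = 1L,
                               start_offset = 0) {
  mode <- match.arg(mode)
  if (inherits(profiles_1, "kick_profile")) profiles_1 <- list(profiles_1)
  if (inherits(profiles_2, "kick_profile")) profiles_2 <- list(profiles_2)
  if (mode == "single") {
    starts <- start_offset
    if (length(profiles_1) > 1L)
      for (i in 2:length(profiles_1))
        starts[i] <- starts[i - 1] + kick_duration(profiles_1[[i - 1]]) + gap
    entries <- data.frame(start_time = starts,
                          actuator_id = rep(1L, length(profiles_1)))
    entries$profile <- profiles_1
  } else if (mode == "dual_simultaneous") {
    if (length(profiles_1) != length(profiles_2))
      stop("dual_simultaneous requires equal kick counts per actuator")
    starts <- start_offset
    if (length(profiles_1) > 1L)
      for (i in 2:length(profiles_1))
        starts[i] <- starts[i - 1] +
          max(kick_duration(profiles_1[[i - 1]]),
              kick_duration(profiles_2[[i - 1]])) + gap
    entries <- data.frame(
      start_time = rep(starts, each = 2L),
      actuator_id = rep(c(1L, 2L), length(starts)))
    entries$profile <- unlist(Map(list, profiles_1, profiles_2),
                              recursive = FALSE)
  } else if (mode == "dual_consecutive") {
    k1 <- length(profiles_1); k2 <- length(profiles_2)
    n <- k1 + k2
    ids <- integer(n); prof <- vector("list", n)
    i1 <- i2 <- 0L
    for (i in seq_len(n)) {
      use1 <- if (i %% 2L == 1L) i1 < k1 else i2 >= k2
      if (use1) { i1 <- i1 + 1L; ids[i] <- 1L; prof[[i]] <- profiles_1[[i1]] }
      else      { i2 <- i2 + 1L; ids[i] <- 2L; prof[[i]] <- profiles_2[[i2]] }
    }
    starts <- start_offset
    if (n > 1L)
      for (i in 2:n)
        starts[i] <- starts[i - 1] + kick_duration(prof[[i - 1]]) + gap
    entries <- data.frame(start_time = starts, actuator_id = ids)
    entries$profile <- prof
  } else { # dual_random
    n1 <- length(profiles_1); n2 <- length(profiles_2)
    starts <- with_seed(seed, stats::runif(n1 + n2, min = start_offset,
                                           max = start_offset + session))
    entries <- data.frame(start_time = starts,
                          actuator_id = c(rep(1L, n1), rep(2L, n2)))
    entries$profile <- c(profiles_1, profiles_2)
  }
  kick_schedule(entries, mode)
}

#' Time span of a schedule
#'
#' @param schedule A [kick_schedule()].
#' @return End time (s) of the last kick.
#' @export
schedule_end <- function(schedule) {
  stopifnot(inherits(schedule, "kick_schedule"))
  if (nrow(schedule$entries) == 0L) return(0)
  max(mapply(function(s, p) s + kick_duration(p),
             schedule$entries$start_time, schedule$entries$profile))
}
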