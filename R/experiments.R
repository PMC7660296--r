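#' Experiment specification
#'
#' Describes one of the case-study experiment designs run on the virtual
#' rig: a wall-displacement sweep, a kick-distance sweep, a
#' detection-threshold study, or a comparative sensor-response study.
#'
#' @param kind Experiment kind.
#' @param sweep Numeric sweep values (m): wall displacements for
#'   `displacement_sweep` / `threshold_study`, sensor distances for
#'   `distance_sweep`. Defaults follow the case-study designs:
#'   2-14 mm displacements, 0-15 cm distances, 0.5 mm threshold steps.
#' @param repetitions Kicks per condition (default 10), >= 1.
#' @param probe Kicking probe (hemispherical for the sweeps, cylindrical —
#'   the weaker probe — for the threshold study).
#' @param distance Sensor distance (m) for fixed-distance designs.
#' @param displacement Wall displacement (m) for fixed-displacement designs.
#' @param seed Master seed; per-repetition seeds derive deterministically
#'   from it (see [derive_seed()]).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(kind = c("displacement_sweep", "distance_sweep",
                                     "threshold_study", "comparative_response"),
                            sweep = NULL, repetitions = 10L,
                            probe = NULL, distance = NULL,
                            displacement = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (repetitions < 1L) stop("repetitions must be >= 1")
  defaults <- switch(kind,
    displacement_sweep = list(sweep = seq(2e-3, 14e-3, by = 2e-3),
                              probe = "hemispherical_30mm", distance = 0.05),
    distance_sweep = list(sweep = seq(0, 0.15, by = 0.03),
                          probe = "hemispherical_30mm", displacement = 10e-3),
    threshold_study = list(sweep = seq(0.5e-3, 5e-3, by = 0.5e-3),
                           probe = "cylindrical_10mm", distance = 0.20),
    comparative_response = list(sweep = numeric(),
                                probe = "hemispherical_30mm", distance = 0.05,
                                displacement = 14e-3))
  spec <- utils::modifyList(defaults,
    Filter(Negate(is.null), list(sweep = sweep, probe = probe,
                                 distance = distance,
                                 displacement = displacement)))
  spec$kind <- kind
  spec$repetitions <- as.integer(repetitions)
  spec$seed <- as.integer(seed)
  if (kind %in% c("displacement_sweep", "threshold_study") &&
      any(spec$sweep < MIN_WALL_DISPLACEMENT - 1e-12))
    stop("sweep displacements below the actuator repeatability floor")
  structure(spec, class = "experiment_spec")
}

#' Deterministic per-repetition seed
#'
#' Splitting rule `master * 10007 + condition * 211 + repetition`, reduced
#' modulo 2^31 - 1, so every individual synthetic kick is independently
#' reproducible from the master seed.
#'
#' @param master Master seed.
#' @param condition Condition index (1-based).
#' @param repetition Repetition index (1-based).
#' @return Integer seed.
#' @export
derive_seed <- function(master, condition, repetition) {
  as.integer((as.double(master) * 10007 + condition * 211 + repetition) %%
               2147483647)
}

# Place the impact point and the sensor symmetrically about the membrane
# centre along a diagonal, as on the rig (the centre is the midpoint between
# sensor and impact point).
placement_for_distance <- function(distance) {
  u <- c(1, 1) / sqrt(2)
  list(impact = -u * distance / 2, sensor = u * distance / 2)
}

#' Synthesize one instrumented kick
#'
#' Builds a single-kick schedule with a quiet lead-in, places the default
#' sensor set at the requested distance from the impact point (symmetric
#' about the membrane centre), and synthesizes the recording.
#'
#' @param displacement Wall displacement (m).
#' @param distance Sensor-to-impact distance (m).
#' @param probe Kicking probe.
#' @param seed Recording seed.
#' @param sensors Named list of [sensor_model()]s (default packaged set);
#'   all are placed at the same point.
#' @param membrane A [membrane_response_model()].
#' @param geometry A [flat_geometry()].
#' @param Fs Sampling rate (Hz).
#' @param lead_in Quiet time before the kick (s), default 4.
#' @param tail Quiet time after the kick (s), default 2.5.
#' @return A `sensor_recording`.
#' @export
synthesize_kick <- function(displacement, distance, probe = "hemispherical_30mm",
                            seed = 1L, sensors = default_sensor_models(),
                            membrane = default_membrane_model(),
                            geometry = testbed_membrane(30)$geometry,
                            Fs = 2000, lead_in = 4, tail = 2.5) {
  pl <- placement_for_distance(distance)
  prof <- kick_profile(displacement, probe = probe, impact_point = pl$impact)
  sch <- schedule_from_mode("single", list(prof), start_offset = lead_in)
  placed <- lapply(sensors, function(m) list(model = m, position = pl$sensor))
  synthesize_recording(sch, placed, membrane = membrane, geometry = geometry,
                       Fs = Fs, duration = lead_in + kick_duration(prof) + tail,
                       seed = seed)
}

aggregate_reps <- function(rows) {
  # rows: data.frame(condition, sensor, snr, energy, mode) over repetitions
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else 0)
  out <- do.call(rbind, lapply(split(rows, list(rows$condition, rows$sensor),
                                     drop = TRUE), function(g) {
    s <- agg(g$snr); e <- agg(g$energy); m <- agg(g$mode)
    data.frame(condition = g$condition[1], sensor = g$sensor[1],
               snr_mean = s[1], snr_sd = s[2],
               energy_mean = e[1], energy_sd = e[2],
               mode_mean = m[1], mode_sd = m[2],
               n = nrow(g), n_snr_undefined = sum(is.na(g$snr)))
  }))
  out <- out[order(out$condition, out$sensor), ]
  rownames(out) <- NULL
  out
}

run_sweep <- function(spec, vary = c("displacement", "distance"), ...) {
  vary <- match.arg(vary)
  rows <- list()
  for (ci in seq_along(spec$sweep)) {
    val <- spec$sweep[ci]
    for (rep in seq_len(spec$repetitions)) {
      seed <- derive_seed(spec$seed, ci, rep)
      rec <- if (vary == "displacement")
        synthesize_kick(val, spec$distance, spec$probe, seed, ...)
      else
        synthesize_kick(spec$displacement, val, spec$probe, seed, ...)
      an <- analyze_recording(rec)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = val, sensor = an$sensor, snr = an$snr,
        energy = an$E_S, mode = an$dominant_mode)
    }
  }
  res <- aggregate_reps(do.call(rbind, rows))
  structure(list(spec = spec, result = res), class = "experiment_result")
}

#' Wall-displacement sweep
#'
#' Repeats kicks over a range of wall displacements at a fixed sensor
#' distance (default 2-14 mm, hemispherical probe, 5 cm) and aggregates the
#' per-sensor SNR, signal energy and dominant mode as mean and standard
#' deviation over the repetitions.
#'
#' @param spec An [experiment_spec()] of kind `displacement_sweep` (a bare
#'   master seed is also accepted).
#' @param ... Passed to [synthesize_kick()] (custom sensors, membrane, ...).
#' @return An `experiment_result`: list with `spec` and `result`
#'   (data.frame, one row per condition x sensor).
#' @export
run_displacement_sweep <- function(spec = experiment_spec("displacement_sweep"),
                                   ...) {
  if (is.numeric(spec))
    spec <- experiment_spec("displacement_sweep", seed = spec)
  stopifnot(identical(spec$kind, "displacement_sweep"))
  run_sweep(spec, "displacement", ...)
}

#' Kick-distance sweep
#'
#' Repeats kicks at a fixed wall displacement while varying the
#' sensor-to-impact distance (default 0-15 cm at 10 mm, hemispherical
#' probe).
#'
#' @inheritParams run_displacement_sweep
#' @return An `experiment_result`.
#' @export
run_distance_sweep <- function(spec = experiment_spec("distance_sweep"), ...) {
  if (is.numeric(spec)) spec <- experiment_spec("distance_sweep", seed = spec)
  stopifnot(identical(spec$kind, "distance_sweep"))
  run_sweep(spec, "distance", ...)
}

#' Detection-threshold study
#'
#' Determines the minimum wall displacement each sensor recognizes: starting
#' from the smallest reliable displacement (0.5 mm) and increasing in 0.5 mm
#' steps, a kick is produced with the weaker (cylindrical) probe at the
#' maximum consistent sensor distance (20 cm), and a sensor detects it when
#' its band-passed response holds a supra-threshold run of at least 10 ms
#' inside the kick interval (see [kick_detected()]).
#'
#' @param spec An [experiment_spec()] of kind `threshold_study` (or a master
#'   seed).
#' @param min_run Minimum supra-threshold run (s).
#' @param ... Passed to [synthesize_kick()].
#' @return An `experiment_result` whose `result` has one row per sensor with
#'   its threshold displacement (m); `NA` if nothing within the sweep was
#'   detected.
#' @export
run_threshold_study <- function(spec = experiment_spec("threshold_study"),
                                min_run = 0.010, ...) {
  if (is.numeric(spec)) spec <- experiment_spec("threshold_study", seed = spec)
  stopifnot(identical(spec$kind, "threshold_study"))
  sensors <- NULL
  thr <- list()
  for (ci in seq_along(spec$sweep)) {
    val <- spec$sweep[ci]
    seed <- derive_seed(spec$seed, ci, 1L)
    rec <- synthesize_kick(val, spec$distance, spec$probe, seed, ...)
    Fs <- rec$sampling_rate
    series <- sensor_series(rec)
    if (is.null(sensors)) {
      sensors <- names(series)
      thr <- stats::setNames(rep(NA_real_, length(sensors)), sensors)
    }
    iv <- kick_intervals(rec)[1L, ]
    qs <- auto_quiet_start(rec, 2)
    for (nm in sensors) {
      if (!is.na(thr[[nm]])) next
      V <- bandpass(series[[nm]], Fs, filter_spec("bandpass", c(1, 40)))
      e <- noise_floor(V, Fs, 2, qs)
      h <- 5 * e
      if (kick_detected(V, Fs, h, c(iv$start, iv$end), min_run))
        thr[[nm]] <- val
    }
    if (!anyNA(thr)) break
  }
  res <- data.frame(sensor = names(thr), threshold_displacement = unname(thr))
  structure(list(spec = spec, result = res), class = "experiment_result")
}

#' Comparative sensor-response study
#'
#' Applies repeated 30-week-style kicks (14 mm, hemispherical probe, 5 cm
#' sensor distance by default) and emits, per sensor: the band-passed
#' response of the first repetition, its spectrogram (0.5 s Hann window, 80%
#' overlap), and the Welch PSD averaged over the repetitions (1 s Hann
#' window, 50% overlap).
#'
#' @param spec An [experiment_spec()] of kind `comparative_response` (or a
#'   master seed).
#' @param ... Passed to [synthesize_kick()].
#' @return List of class `comparative_response` with `t`, `response`
#'   (list per sensor), `spectrogram` (list per sensor), `psd` (list per
#'   sensor, repetition-averaged) and `spec`.
#' @export
run_comparative_response <- function(spec = experiment_spec("comparative_response"),
                                     ...) {
  if (is.numeric(spec))
    spec <- experiment_spec("comparative_response", seed = spec)
  stopifnot(identical(spec$kind, "comparative_response"))
  responses <- specs <- psds <- NULL
  for (rep in seq_len(spec$repetitions)) {
    seed <- derive_seed(spec$seed, 1L, rep)
    rec <- synthesize_kick(spec$displacement, spec$distance, spec$probe,
                           seed, ...)
    Fs <- rec$sampling_rate
    series <- sensor_series(rec)
    filt <- lapply(series, bandpass, Fs = Fs,
                   spec = filter_spec("bandpass", c(1, 40)))
    ps <- lapply(filt, welch_psd, Fs = Fs, cfg = spectral_config())
    if (is.null(psds)) {
      psds <- ps
      responses <- filt
      specs <- lapply(filt, spectrogram, Fs = Fs, cfg = spectrogram_config())
      tvec <- rec$t
    } else {
      for (nm in names(ps)) psds[[nm]]$p <- psds[[nm]]$p + ps[[nm]]$p
    }
  }
  for (nm in names(psds)) psds[[nm]]$p <- psds[[nm]]$p / spec$repetitions
  structure(list(t = tvec, response = responses, spectrogram = specs,
                 psd = psds, spec = spec),
            class = "comparative_response")
}

#' Write / read an experiment result table
#'
#' Tab-delimited text with a `#`-prefixed header carrying the experiment
#' kind and master seed; the table round-trips losslessly.
#'
#' @param x An `experiment_result`.
#' @param path Output file.
#' @return `path` invisibly; `read_experiment_result()` returns the
#'   `experiment_result`.
#' @export
write_experiment_result <- function(x, path) {
  stopifnot(inherits(x, "experiment_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", x$spec$kind),
               sprintf("# seed: %d", x$spec$seed)), con)
  utils::write.table(x$result, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_experiment_result
#' @export
read_experiment_result <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kind <- sub("^# kind: ", "", grep("^# kind: ", hdr, value = TRUE))
  seed <- as.integer(sub("^# seed: ", "", grep("^# seed: ", hdr, value = TRUE)))
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  structure(list(spec = list(kind = kind, seed = seed), result = tab),
            class = "experiment_result")
}

#' Save an experiment result with a provenance log
#'
#' Writes `result.tsv` plus a `run_log.yaml` (experiment kind, sweep, seeds,
#' package version, timestamp) into `dir`.
#'
#' @param x An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_experiment <- function(x, dir) {
  stopifnot(inherits(x, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment_result(x, file.path(dir, "result.tsv"))
  log <- list(kind = x$spec$kind,
              sweep = as.numeric(x$spec$sweep),
              repetitions = x$spec$repetitions,
              master_seed = x$spec$seed,
              package_version = as.character(utils::packageVersion("fmsim")),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"))
  yaml::write_yaml(log, file.path(dir, "run_log.yaml"))
  invisible(dir)
}
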