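test_that("actuator trajectory is a trapezoid with the commanded duration", {
  p <- kick_profile(10e-3, probe = "cylindrical_10mm")
  wf <- actuator_waveform(p, 2000)
  expect_equal(wf$duration, 2 * 10e-3 / ACTUATOR_MAX_SPEED, tolerance = 1e-12)
  expect_equal(max(wf$x), 10e-3, tolerance = 1e-5)
  expect_equal(wf$x[1], 0)
  expect_equal(wf$x[length(wf$x)], 0, tolerance = 1e-5)
  expect_equal(nrow(wf$events), 4L)
  expect_equal(wf$events$dv,
               c(1, -1, -1, 1) * ACTUATOR_MAX_SPEED)
  # pause extends the plateau
  pp <- kick_profile(10e-3, pause_at_peak = 0.5, probe = "cylindrical_10mm")
  expect_equal(actuator_waveform(pp, 2000)$duration, wf$duration + 0.5)
})

test_that("kick durations track the rig measurements", {
  # measured durations: cylindrical probe 1.63 s (10 mm), 2.45 s (15 mm)
  d10 <- kick_duration(kick_profile(10e-3, probe = "cylindrical_10mm"))
  d15 <- kick_duration(kick_profile(15e-3, probe = "cylindrical_10mm"))
  expect_equal(d10, 1.63, tolerance = 0.02)
  expect_equal(d15, 2.45, tolerance = 0.02)
  # the derating factor emulates loaded-actuator slowdown
  d10_loaded <- kick_duration(kick_profile(10e-3, speed_derating = 0.95,
                                           probe = "hemispherical_30mm"))
  expect_gt(d10_loaded, d10)
})

test_that("profiles outside the actuator envelope are rejected", {
  expect_error(kick_profile(0.4e-3), "repeatability floor")
  expect_error(kick_profile(40e-3), "membrane-safe")
  expect_error(kick_profile(5e-3, actuator_speed = 0.02), "actuator_speed")
  expect_error(kick_profile(5e-3, angle = 45), "angle")
})

test_that("reaction force interpolates the per-probe calibration knots", {
  expect_equal(reaction_force("cylindrical_10mm", displacement = 10e-3), 14.84)
  expect_equal(reaction_force("cylindrical_10mm", displacement = 15e-3), 33.15)
  expect_equal(reaction_force("hemispherical_30mm", displacement = 10e-3), 26.01)
  expect_equal(reaction_force("hemispherical_30mm", displacement = 15e-3), 44.20)
  # midpoint of the linear interpolation
  expect_equal(reaction_force("hemispherical_30mm", displacement = 12.5e-3),
               35.105)
  # extrapolation is floored at zero
  expect_gte(reaction_force("cylindrical_10mm", displacement = 1e-3), 0)
  p <- kick_profile(12.5e-3, probe = "hemispherical_30mm")
  expect_equal(reaction_force(p), 35.105)
})

test_that("kick modes build the schedules they describe", {
  prof <- kick_profile(10e-3, probe = "cylindrical_10mm")
  Tk <- kick_duration(prof)
  s <- schedule_from_mode("single", list(prof, prof, prof), gap = 10)
  expect_equal(s$entries$start_time, c(0, 10 + Tk, 2 * (10 + Tk)),
               tolerance = 1e-9)

  expect_error(schedule_from_mode("dual_simultaneous", list(prof, prof),
                                  list(prof, prof, prof)),
               "equal kick counts")
  s2 <- schedule_from_mode("dual_simultaneous", list(prof, prof),
                           list(prof, prof))
  st <- s2$entries$start_time
  expect_equal(st[1], st[2])
  expect_equal(st[3], st[4])

  s3 <- schedule_from_mode("dual_consecutive", list(prof, prof), list(prof))
  expect_equal(s3$entries$actuator_id, c(1L, 2L, 1L))
  # non-overlapping
  expect_true(all(diff(s3$entries$start_time) >= Tk))

  s4 <- schedule_from_mode("dual_random", list(prof), list(prof),
                           session = 60, seed = 11)
  s5 <- schedule_from_mode("dual_random", list(prof), list(prof),
                           session = 60, seed = 11)
  expect_identical(s4$entries$start_time, s5$entries$start_time)
})

test_that("membrane response attenuates exponentially with distance", {
  model <- default_membrane_model()
  p <- kick_profile(10e-3, impact_point = c(-0.06, -0.06))
  r1 <- membrane_response(p, c(-0.06, -0.06), model, Fs = 2000, duration = 4)
  r2 <- membrane_response(p, c(-0.06 + 0.0707, -0.06 + 0.0707), model,
                          Fs = 2000, duration = 4)
  # all response components share the same exponential attenuation
  expect_equal(max(abs(r2$disp)) / max(abs(r1$disp)),
               exp(-0.1 / model$attenuation_length), tolerance = 1e-3)
  expect_error(membrane_response(p, c(1, 1), model,
                                 geometry = testbed30()$geometry),
               "outside the membrane")
})

test_that("free ringing decays by more than 99% within five time constants", {
  # ring-only model (forced coupling suppressed, sway off is not allowed by
  # the validator, so make it negligible)
  for (tau_ring in c(6.4e-3, 0.05, 0.30)) {
    model <- membrane_response_model(ring_decay = tau_ring,
                                     coupling_gain = 1e-9,
                                     slow_mode_fraction = 0)
    p <- kick_profile(10e-3, impact_point = c(0, 0))
    rr <- membrane_response(p, c(0, 0), model, Fs = 2000,
                            duration = kick_duration(p) + 8 * tau_ring)
    t_end <- kick_duration(p)
    early <- abs(rr$disp)[rr$t >= t_end & rr$t <= t_end + tau_ring]
    late <- abs(rr$disp)[rr$t >= t_end + 5 * tau_ring &
                           rr$t <= t_end + 6 * tau_ring]
    expect_lt(max(late) / max(early), 0.02)
  }
})

test_that("synthesis is pure given the seed", {
  sch <- schedule_from_mode("single",
                            list(kick_profile(8e-3,
                                              impact_point = c(-0.03, -0.03))),
                            start_offset = 4)
  sensors <- lapply(default_sensor_models(),
                    function(m) list(model = m, position = c(0.03, 0.03)))
  r1 <- synthesize_recording(sch, sensors, seed = 123)
  r2 <- synthesize_recording(sch, sensors, seed = 123)
  expect_identical(r1$channels, r2$channels)
  r3 <- synthesize_recording(sch, sensors, seed = 124)
  expect_false(identical(r1$channels, r3$channels))
})

test_that("a noiseless, kick-free recording is silent", {
  sensors <- lapply(noiseless_sensors(),
                    function(m) list(model = m, position = c(0, 0)))
  empty <- kick_schedule(data.frame(start_time = numeric(),
                                    actuator_id = integer(),
                                    profile = I(list()))[0, ])
  rec <- synthesize_recording(empty, sensors, duration = 2, seed = 1)
  ch <- rec$channels
  expect_true(all(ch[, c("acoustic", "piezoelectric", "accelerometer_x",
                         "accelerometer_y")] == 0))
  # the z axis carries only the static gravity offset
  expect_equal(unique(round(ch[, "accelerometer_z"], 12)),
               0.0306 * 9.81, tolerance = 1e-6)
})

test_that("quiet segments carry only the configured noise floor", {
  rec <- synthesize_kick(10e-3, 0.05, seed = 9)
  idx <- seq_len(2000 * 3)   # 3 s lead-in, clear of the kick
  sens <- default_sensor_models()
  # folded-normal mean |V| = rms * sqrt(2/pi), within 5% at n >= 1e4
  expect_equal(mean(abs(rec$channels[idx, "acoustic"])),
               sens$acoustic$noise_floor_rms * sqrt(2 / pi),
               tolerance = 0.05)
  expect_equal(mean(abs(rec$channels[idx, "accelerometer_x"])),
               sens$accelerometer$noise_floor_rms * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("sensor passbands above Nyquist are rejected", {
  sch <- schedule_from_mode("single", list(kick_profile(5e-3)))
  bad <- sensor_model("acoustic", passband = c(1, 100))
  expect_error(synthesize_recording(sch, list(list(model = bad,
                                                   position = c(0, 0))),
                                    Fs = 150, seed = 1),
               "Nyquist")
})

test_that("recordings round-trip through the delimited text format", {
  rec <- synthesize_kick(6e-3, 0.05, seed = 21, lead_in = 3, tail = 1)
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$seed, rec$seed)
  expect_equal(colnames(back$channels), colnames(rec$channels))
  expect_equal(unname(back$channels), unname(signif(rec$channels, 9L)),
               tolerance = 1e-9)
  unlink(path)
})
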