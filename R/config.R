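fmsim_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fmsim")
  if (!nzchar(path)) stop("packaged config not found: ", file)
  path
}

kPa <- function(x) x * 1e3
mm <- function(x) x * 1e-3

#' Reference abdominal tissue layers
#'
#' Loads the packaged table of reported material and geometrical properties
#' of the maternal abdomen layers (30-week gestational age) as
#' [tissue_layer()] objects, in SI units.
#'
#' @param file Optional path to a user configuration in the same YAML layout.
#' @return A named list of [tissue_layer()] objects.
#' @export
abdomen_layers <- function(file = fmsim_extdata("abdomen_layers.yaml")) {
  cfg <- yaml::read_yaml(file)
  out <- lapply(cfg$layers, function(l) {
    rng <- list()
    if (!is.null(l$youngs_modulus_range_kPa))
      rng$youngs_modulus <- kPa(unlist(l$youngs_modulus_range_kPa))
    if (!is.null(l$thickness_range_mm))
      rng$thickness <- mm(unlist(l$thickness_range_mm))
    if (!is.null(l$density_range_kg_m3))
      rng$density <- unlist(l$density_range_kg_m3)
    tissue_layer(
      name = l$name,
      youngs_modulus = kPa(l$youngs_modulus_kPa),
      poisson_ratio = l$poisson_ratio,
      thickness = mm(l$thickness_mm),
      density = if (is.null(l$density_kg_m3)) NA_real_ else l$density_kg_m3,
      ranges = rng)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Canonical curved-abdomen reference model
#'
#' The published weighted-average single-layer material of the 30-week
#' gravid abdomen together with its curved design geometry (equal radii of
#' curvature; side lengths equal to the semicircumference at that radius).
#' These printed values are shipped as-is and override on-the-fly layer
#' aggregation, whose exact published weighting is not reproducible.
#'
#' @param file Optional path to a user configuration.
#' @return List with elements `material` (a [composite_membrane()]) and
#'   `geometry` (a [curved_geometry()]).
#' @export
abdomen_reference <- function(file = fmsim_extdata("abdomen_layers.yaml")) {
  cfg <- yaml::read_yaml(file)
  w <- cfg$weighted_average
  mat <- composite_membrane(
    youngs_modulus = kPa(w$youngs_modulus_kPa),
    poisson_ratio = w$poisson_ratio,
    density = w$density_kg_m3,
    thickness = mm(w$thickness_mm))
  R <- mm(cfg$geometry$radius_of_curvature_mm)
  geo <- curved_geometry(side_a = pi * R, side_b = pi * R,
                         radius_A = R, radius_B = R,
                         thickness = mat$thickness)
  list(material = mat, geometry = geo)
}

#' Silicone phantom materials
#'
#' Loads the packaged silicone variant table. The testbed entry names the
#' selected membrane material and the as-built clamped side length and
#' thickness.
#'
#' @param file Optional path to a user configuration.
#' @return List with `silicones` (named list of [composite_membrane()],
#'   thickness set to the testbed thickness) and `testbed`
#'   (`material` name, `clamped_side` m, `thickness` m).
#' @export
silicone_materials <- function(file = fmsim_extdata("silicones.yaml")) {
  cfg <- yaml::read_yaml(file)
  h <- mm(cfg$testbed$thickness_mm)
  sil <- lapply(cfg$silicones, function(s)
    composite_membrane(kPa(s$youngs_modulus_kPa), min(s$poisson_ratio, 0.5 - 1e-9),
                       s$density_kg_m3, h))
  names(sil) <- vapply(cfg$silicones, `[[`, "", "name")
  list(silicones = sil,
       testbed = list(material = cfg$testbed$material,
                      clamped_side = mm(cfg$testbed$clamped_side_mm),
                      thickness = h))
}

#' Uterine wall tensions by gestational age
#'
#' @param file Optional path to a user configuration.
#' @return data.frame with columns `gestation_weeks`, `stress` (Pa),
#'   `stress_min`, `stress_max` (Pa).
#' @export
gestational_tensions <- function(file = fmsim_extdata("gestation_tensions.yaml")) {
  cfg <- yaml::read_yaml(file)
  do.call(rbind, lapply(cfg$tensions, function(t)
    data.frame(gestation_weeks = t$gestation_weeks,
               stress = kPa(t$stress_kPa),
               stress_min = kPa(t$stress_range_kPa[[1]]),
               stress_max = kPa(t$stress_range_kPa[[2]]))))
}

#' Stretched testbed membrane at a gestational age
#'
#' Builds the flat testbed geometry in its clamped, prestressed state:
#' clamped side length plus the biaxial prestress elongation for the mean
#' uterine wall tension of the requested gestational age, rounded to the
#' nearest millimetre as applied on the rig.
#'
#' @param gestation_weeks One of the configured ages (20, 25, 30).
#' @param round_elongation_mm Round the applied elongation to whole
#'   millimetres, as the stretching mechanism does (default `TRUE`).
#' @return List with `geometry` ([flat_geometry()]), `material`
#'   ([composite_membrane()]), `elongation` (m, exact) and `stress` (Pa).
#' @export
testbed_membrane <- function(gestation_weeks = 30, round_elongation_mm = TRUE) {
  sil <- silicone_materials()
  mat <- sil$silicones[[sil$testbed$material]]
  tens <- gestational_tensions()
  row <- tens[tens$gestation_weeks == gestation_weeks, ]
  if (nrow(row) != 1L)
    stop("no configured tension for gestation week ", gestation_weeks)
  a0 <- sil$testbed$clamped_side
  delta <- prestress_elongation(a0, row$stress, mat$youngs_modulus,
                                mat$poisson_ratio)
  applied <- if (round_elongation_mm) round(delta, 3) else delta
  geo <- flat_geometry(side_a = a0 + applied, side_b = a0 + applied,
                       thickness = sil$testbed$thickness,
                       prestress = row$stress)
  list(geometry = geo, material = mat, elongation = delta, stress = row$stress)
}

#' Default membrane response model for the kick synthesizer
#'
#' @param file Optional path to a user configuration.
#' @return A [membrane_response_model()] built from the packaged calibrated
#'   defaults.
#' @export
default_membrane_model <- function(file = fmsim_extdata("membrane_model.yaml")) {
  m <- yaml::read_yaml(file)$membrane_model
  membrane_response_model(
    f_nd = m$f_nd_hz,
    ring_decay = m$ring_decay_s,
    attenuation_length = m$attenuation_length_m,
    coupling_gain = m$coupling_gain,
    forced_smoothing = m$forced_smoothing_s,
    ring_amplitude = m$ring_amplitude_m,
    ring_ref_displacement = mm(m$ring_ref_displacement_mm),
    ring_exponent = m$ring_exponent,
    slow_mode_fraction = m$slow_mode_fraction,
    slow_mode_freq = m$slow_mode_freq_hz,
    slow_mode_decay = m$slow_mode_decay_s,
    slow_mode_exponent = m$slow_mode_exponent)
}

#' Default sensor models
#'
#' @param file Optional path to a user configuration.
#' @return Named list of [sensor_model()] objects
#'   (`acoustic`, `piezoelectric`, `accelerometer`).
#' @export
default_sensor_models <- function(file = fmsim_extdata("sensors.yaml")) {
  cfg <- yaml::read_yaml(file)
  out <- lapply(cfg$sensors, function(s)
    sensor_model(kind = s$kind,
                 passband = unlist(s$passband_hz),
                 sensitivity = s$sensitivity,
                 noise_floor_rms = s$noise_floor_rms,
                 lowpass = if (!is.null(s$lowpass_hz)) s$lowpass_hz else NA_real_,
                 lowpass_order = if (!is.null(s$lowpass_order)) s$lowpass_order else 4L,
                 bandwidth = if (!is.null(s$bandwidth_hz)) s$bandwidth_hz else NA_real_,
                 gravity_offset = isTRUE(s$gravity_offset)))
  names(out) <- vapply(cfg$sensors, `[[`, "", "kind")
  out
}
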