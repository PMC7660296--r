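#' Membrane design report
#'
#' Chains the design workflow end-to-end: the curved-abdomen reference model
#' gives the target natural frequency; the flat silicone testbed is sized to
#' match it; the prestress elongation for the requested gestational age is
#' computed; and the vibration characteristics of the as-built stretched
#' membrane (optionally against a measured damped frequency) are reported.
#'
#' @param gestation_weeks Gestational age (20, 25 or 30).
#' @param f_nd Measured damped natural frequency of the stretched membrane
#'   (Hz), default the reference 18.70; `NA` skips the damping-derived rows.
#' @return data.frame with columns `quantity`, `value`, `units`.
#' @export
membrane_design_report <- function(gestation_weeks = 30, f_nd = 18.70) {
  ref <- abdomen_reference()
  f_curved <- natural_frequency_curved(ref$geometry, ref$material)
  tb <- testbed_membrane(gestation_weeks)
  side_req <- side_length_for_frequency(f_curved, tb$material,
                                        h = tb$geometry$thickness)
  vib <- vibration_characteristics(tb$geometry, tb$material, f_nd)
  rows <- data.frame(
    quantity = c("curved abdomen natural frequency",
                 "required flat square side for that frequency",
                 "clamped testbed side",
                 "prestress elongation per axis",
                 "stretched testbed side",
                 "stretched testbed natural frequency (undamped)",
                 "measured damped natural frequency",
                 "damping ratio",
                 "damping coefficient",
                 "time constant"),
    value = c(f_curved, side_req * 1e3,
              (tb$geometry$side_a - round(tb$elongation, 3)) * 1e3,
              tb$elongation * 1e3, tb$geometry$side_a * 1e3,
              vib$f_n, f_nd, vib$damping_ratio,
              vib$damping_coefficient, vib$time_constant * 1e3),
    units = c("Hz", "mm", "mm", "mm", "mm", "Hz", "Hz", "", "N.s/m", "ms"))
  rows
}
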