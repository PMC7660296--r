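#' Thickness-weighted composite membrane properties
#'
#' Aggregates abdominal tissue layers into the equivalent single-layer
#' membrane: Young's modulus and Poisson's ratio are thickness-weighted means
#' over all layers; the density is a thickness-weighted mean over
#' `density_layers` only (the fetal membrane has no reported density, so only
#' the uterine and abdominal walls contribute); the thickness is the sum of
#' all layer thicknesses.
#'
#' Note that the reference weighted-average property table for the
#' 30-week abdomen is not exactly reproduced by this arithmetic (direct
#' weighting of the published layer values gives E near 157 kPa against the
#' published weighted 151.37 kPa); the published weighted row is therefore
#' shipped as the canonical curved-abdomen configuration (see
#' [abdomen_reference()]) and this function serves for user-supplied layer
#' tables.
#'
#' @param layers List of [tissue_layer()] objects (at least one).
#' @param density_layers Character vector of layer names over which the
#'   density is weighted. Every named layer must exist and carry a density.
#' @return A [composite_membrane()].
#' @export
composite_properties <- function(layers,
                                 density_layers = vapply(layers, `[[`, "",
                                                         "name")) {
  if (length(layers) == 0L) stop("at least one layer is required")
  if (!all(vapply(layers, inherits, TRUE, "tissue_layer")))
    stop("layers must be tissue_layer objects")
  if (length(density_layers) == 0L) stop("density_layers must be non-empty")
  nms <- vapply(layers, `[[`, "", "name")
  unknown <- setdiff(density_layers, nms)
  if (length(unknown))
    stop("unknown layer name(s) in density_layers: ",
         paste(unknown, collapse = ", "))
  h <- vapply(layers, `[[`, 0, "thickness")
  E <- vapply(layers, `[[`, 0, "youngs_modulus")
  mu <- vapply(layers, `[[`, 0, "poisson_ratio")
  rho <- vapply(layers, `[[`, NA_real_, "density")
  di <- match(density_layers, nms)
  if (anyNA(rho[di]))
    stop("layer(s) without density named in density_layers: ",
         paste(density_layers[is.na(rho[di])], collapse = ", "))
  mu_c <- sum(mu * h) / sum(h)
  # a composite at exactly 0.5 would make the flexural rigidity singular
  mu_c <- min(mu_c, 0.5 - 1e-9)
  composite_membrane(
    youngs_modulus = sum(E * h) / sum(h),
    poisson_ratio  = mu_c,
    density        = sum(rho[di] * h[di]) / sum(h[di]),
    thickness      = sum(h))
}

#' Flexural rigidity of a plate or membrane
#'
#' \eqn{D = E h^3 / (12 (1 - \mu^2))} (Pa m\eqn{^3}).
#'
#' @param E Young's modulus (Pa), > 0.
#' @param h Thickness (m), >= 0.
#' @param mu Poisson's ratio, in \[0, 1).
#' @return Flexural rigidity (Pa m\eqn{^3}).
#' @export
flexural_rigidity <- function(E, h, mu) {
  stopifnot(is.finite(E), E > 0, is.finite(h), h >= 0)
  if (!is.finite(mu) || mu < 0 || mu >= 1)
    stop("poisson ratio must be in [0, 1) for the flexural rigidity")
  E * h^3 / (12 * (1 - mu^2))
}

#' Natural frequency of a curved clamped rectangular membrane
#'
#' Rayleigh-method closed form for the first mode of the doubly curved
#' clamped membrane used as the design model of the gravid abdomen:
#' \deqn{f_n = \frac{1}{2\pi}\sqrt{\frac{D}{\rho h}\left[
#'   72\left(\frac{7}{a^4}+\frac{7}{b^4}+\frac{4}{a^2 b^2}\right) +
#'   \frac{12}{h^2}\left(\frac{1}{A^2}+\frac{1}{B^2}+\frac{2\mu}{AB}\right)
#' \right]}}
#' In the flat limit (\eqn{A, B \to \infty}) the bracket tends to the
#' Rayleigh constant \eqn{72 \cdot 18 = 1296} on a square, within 1% of the
#' Galerkin constant \eqn{36.11^2} of [natural_frequency_flat()].
#'
#' @param geom A [curved_geometry()].
#' @param mat A [composite_membrane()].
#' @return Undamped natural frequency (Hz).
#' @export
natural_frequency_curved <- function(geom, mat) {
  stopifnot(inherits(geom, "curved_geometry"),
            inherits(mat, "composite_membrane"))
  D <- flexural_rigidity(mat$youngs_modulus, geom$thickness, mat$poisson_ratio)
  a <- geom$side_a; b <- geom$side_b
  A <- geom$radius_A; B <- geom$radius_B
  h <- geom$thickness; mu <- mat$poisson_ratio
  brack <- 72 * (7 / a^4 + 7 / b^4 + 4 / (a^2 * b^2)) +
    (12 / h^2) * (1 / A^2 + 1 / B^2 + 2 * mu / (A * B))
  sqrt(D / (mat$density * h) * brack) / (2 * pi)
}

#' Natural frequency of a flat clamped membrane (undamped)
#'
#' Galerkin closed form for the first mode of a clamped flat membrane:
#' \eqn{f_n = \frac{1}{2\pi}\sqrt{\Lambda D / (\rho h a^3 b)}} with
#' \eqn{\Lambda = 36.11^2} for a square membrane.
#'
#' @param geom A [flat_geometry()].
#' @param mat A [composite_membrane()].
#' @param Lambda Mode constant; defaults to [LAMBDA_SQUARE_MODE1].
#' @return Undamped natural frequency (Hz).
#' @export
natural_frequency_flat <- function(geom, mat, Lambda = LAMBDA_SQUARE_MODE1) {
  stopifnot(inherits(geom, "flat_geometry"),
            inherits(mat, "composite_membrane"))
  D <- flexural_rigidity(mat$youngs_modulus, geom$thickness, mat$poisson_ratio)
  sqrt(Lambda * D / (mat$density * geom$thickness *
                       geom$side_a^3 * geom$side_b)) / (2 * pi)
}

#' Square side length achieving a target flat-membrane frequency
#'
#' Inverts the flat-membrane frequency formula for a square membrane:
#' \eqn{a = (\Lambda D / (\rho h))^{1/4} / \sqrt{2\pi f}}.
#'
#' @param target_f Target undamped natural frequency (Hz), > 0.
#' @param mat A [composite_membrane()].
#' @param h Membrane thickness (m); defaults to the composite thickness.
#' @param Lambda Mode constant; defaults to [LAMBDA_SQUARE_MODE1].
#' @return Side length (m) of the square membrane.
#' @export
side_length_for_frequency <- function(target_f, mat, h = mat$thickness,
                                      Lambda = LAMBDA_SQUARE_MODE1) {
  stopifnot(inherits(mat, "composite_membrane"))
  if (!is.finite(target_f) || target_f <= 0) stop("target_f must be > 0")
  D <- flexural_rigidity(mat$youngs_modulus, h, mat$poisson_ratio)
  (Lambda * D / (mat$density * h))^(1 / 4) / sqrt(2 * pi * target_f)
}

#' Natural frequency of free damped vibration of a flat membrane
#'
#' \eqn{f_{nd} = \frac{1}{2\pi}\sqrt{\Lambda D/(\rho h a^3 b) -
#' (k/(2\rho h))^2}} where \eqn{k} is the viscous damping coefficient.
#' With `k = 0` this reduces exactly to [natural_frequency_flat()].
#'
#' @param geom A [flat_geometry()].
#' @param mat A [composite_membrane()].
#' @param k Damping coefficient (N s/m), >= 0.
#' @param Lambda Mode constant.
#' @return Damped natural frequency (Hz).
#' @export
damped_natural_frequency <- function(geom, mat, k,
                                     Lambda = LAMBDA_SQUARE_MODE1) {
  stopifnot(inherits(geom, "flat_geometry"),
            inherits(mat, "composite_membrane"))
  if (!is.finite(k) || k < 0) stop("k must be >= 0")
  D <- flexural_rigidity(mat$youngs_modulus, geom$thickness, mat$poisson_ratio)
  rh <- mat$density * geom$thickness
  rad <- Lambda * D / (rh * geom$side_a^3 * geom$side_b) - (k / (2 * rh))^2
  if (rad <= 0)
    stop("overdamped membrane: damping at or beyond critical, no oscillation",
         call. = FALSE)
  sqrt(rad) / (2 * pi)
}

#' Damping coefficient implied by measured frequencies
#'
#' Inverts the damped-frequency relation: given the undamped natural
#' frequency \eqn{f_n} (from the closed form) and the measured damped natural
#' frequency \eqn{f_{nd}},
#' \eqn{k = 2\rho h \sqrt{(2\pi f_n)^2 - (2\pi f_{nd})^2}}.
#'
#' @param f_n Undamped natural frequency (Hz).
#' @param f_nd Measured damped natural frequency (Hz), 0 < `f_nd` < `f_n`.
#' @param rho Density (kg/m\eqn{^3}).
#' @param h Thickness (m).
#' @return Damping coefficient (N s/m).
#' @export
damping_coefficient_from_measured <- function(f_n, f_nd, rho, h) {
  stopifnot(is.finite(f_n), is.finite(f_nd), rho > 0, h > 0)
  if (f_nd <= 0 || f_nd >= f_n)
    stop("f_nd must satisfy 0 < f_nd < f_n")
  2 * rho * h * sqrt((2 * pi * f_n)^2 - (2 * pi * f_nd)^2)
}

#' Damping ratio from the measured damped frequency
#'
#' \eqn{\zeta = \sqrt{1 - \rho h a^3 b (2\pi f_{nd})^2 / (\Lambda D)}}, which
#' equals \eqn{\sqrt{1 - (f_{nd}/f_n)^2}}. The square root is explicit: only
#' this form is a valid fraction of critical damping (it maps
#' \eqn{f_{nd} = f_n} to 0 and \eqn{f_{nd} = 0} to 1).
#'
#' @param geom A [flat_geometry()].
#' @param mat A [composite_membrane()].
#' @param f_nd Measured damped natural frequency (Hz), > 0.
#' @param Lambda Mode constant.
#' @return Damping ratio in \[0, 1\].
#' @export
damping_ratio <- function(geom, mat, f_nd, Lambda = LAMBDA_SQUARE_MODE1) {
  if (!is.finite(f_nd) || f_nd <= 0) stop("f_nd must be > 0")
  f_n <- natural_frequency_flat(geom, mat, Lambda)
  if (f_nd > f_n * (1 + 1e-12))
    stop("f_nd exceeds the undamped natural frequency of this membrane")
  sqrt(max(0, 1 - (f_nd / f_n)^2))
}

#' Vibration decay time constant
#'
#' \eqn{\tau = 2\rho h / k}: the e-folding time of the free-vibration
#' amplitude envelope of the single-mode viscous model. The amplitude decays
#' by more than 99% within \eqn{5\tau}.
#'
#' @param rho Density (kg/m\eqn{^3}).
#' @param h Thickness (m).
#' @param k Damping coefficient (N s/m), > 0.
#' @return Time constant (s).
#' @export
time_constant <- function(rho, h, k) {
  stopifnot(rho > 0, h > 0)
  if (!is.finite(k) || k <= 0) stop("k must be > 0")
  2 * rho * h / k
}

#' Biaxial strains under plane stress
#'
#' Hooke's law for biaxial loading of an isotropic sheet:
#' \eqn{\epsilon_x = (\sigma_x - \mu\sigma_y)/E},
#' \eqn{\epsilon_y = (\sigma_y - \mu\sigma_x)/E}.
#'
#' @param sigma_x,sigma_y Normal stresses along X and Y (Pa).
#' @param E Young's modulus (Pa), > 0.
#' @param mu Poisson's ratio.
#' @return Named numeric vector `c(eps_x, eps_y)`.
#' @export
biaxial_strains <- function(sigma_x, sigma_y, E, mu) {
  if (!is.finite(E) || E <= 0) stop("E must be > 0")
  c(eps_x = (sigma_x - mu * sigma_y) / E,
    eps_y = (sigma_y - mu * sigma_x) / E)
}

#' Prestress elongation of a square membrane
#'
#' Elongation \eqn{\delta = a \sigma (1 - \mu) / E} along each axis required
#' to impose an equal biaxial tension \eqn{\sigma} on a clamped square
#' membrane of side \eqn{a}, emulating the uterine wall tension at a given
#' gestational age.
#'
#' @param a Clamped side length (m), > 0.
#' @param sigma Target biaxial tensile stress (Pa), >= 0.
#' @param E Young's modulus (Pa), > 0.
#' @param mu Poisson's ratio.
#' @return Elongation (m) along each axis.
#' @export
prestress_elongation <- function(a, sigma, E, mu) {
  stopifnot(is.finite(a), a > 0)
  if (!is.finite(E) || E <= 0) stop("E must be > 0")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  a * sigma * (1 - mu) / E
}

#' Vibration characteristics summary of a flat testbed membrane
#'
#' Convenience wrapper chaining the closed forms: given the stretched flat
#' geometry, the membrane material and a measured damped natural frequency,
#' computes the undamped frequency, damping coefficient, damping ratio and
#' time constant.
#'
#' @param geom A [flat_geometry()].
#' @param mat A [composite_membrane()].
#' @param f_nd Measured damped natural frequency (Hz); `NA` to skip the
#'   damping-derived quantities.
#' @param Lambda Mode constant.
#' @return A list of class `vibration_characteristics` with elements `f_n`,
#'   `f_nd`, `damping_ratio`, `damping_coefficient`, `time_constant`,
#'   `mode_constant`.
#' @export
vibration_characteristics <- function(geom, mat, f_nd = NA_real_,
                                      Lambda = LAMBDA_SQUARE_MODE1) {
  f_n <- natural_frequency_flat(geom, mat, Lambda)
  out <- list(f_n = f_n, f_nd = f_nd, damping_ratio = NA_real_,
              damping_coefficient = NA_real_, time_constant = NA_real_,
              mode_constant = Lambda)
  if (!is.na(f_nd)) {
    out$damping_ratio <- damping_ratio(geom, mat, f_nd, Lambda)
    k <- damping_coefficient_from_measured(f_n, f_nd, mat$density,
                                           geom$thickness)
    out$damping_coefficient <- k
    out$time_constant <- time_constant(mat$density, geom$thickness, k)
  }
  structure(out, class = "vibration_characteristics")
}

#' @export
print.vibration_characteristics <- function(x, ...) {
  cat(sprintf("<vibration_characteristics> f_n = %.2f Hz", x$f_n))
  if (!is.na(x$f_nd))
    cat(sprintf(", f_nd = %.2f Hz, zeta = %.2f, tau = %.2g ms",
                x$f_nd, x$damping_ratio, x$time_constant * 1e3))
  cat("\n")
  invisible(x)
}
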