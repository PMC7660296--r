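#' Tissue layer of the maternal abdomen
#'
#' A single anatomical layer (fetal membrane, uterine wall, abdominal wall)
#' with the material and geometrical properties that enter the membrane
#' vibration model. All quantities are strict SI: Pa, kg/m\eqn{^3}, m.
#'
#' @param name Layer name.
#' @param youngs_modulus Young's modulus \eqn{E} (Pa), > 0.
#' @param poisson_ratio Poisson's ratio \eqn{\mu}, in \[0, 0.5\]. 0.5 marks an
#'   incompressible layer and is accepted for aggregation inputs.
#' @param thickness Layer thickness \eqn{h} (m), > 0.
#' @param density Density \eqn{\rho} (kg/m\eqn{^3}), or `NA` when unreported.
#' @param ranges Optional named list of `c(min, max)` ranges per field
#'   (e.g. `list(youngs_modulus = c(3.2e6, 13.7e6))`); each range must bracket
#'   the mean.
#'
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, youngs_modulus, poisson_ratio, thickness,
                         density = NA_real_, ranges = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be > 0")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("poisson_ratio must be in [0, 0.5]")
  if (!is.finite(thickness) || thickness <= 0)
    stop("thickness must be > 0")
  if (!is.na(density) && density <= 0)
    stop("density must be > 0 when given")
  vals <- list(youngs_modulus = youngs_modulus, poisson_ratio = poisson_ratio,
               thickness = thickness, density = density)
  for (fld in names(ranges)) {
    rng <- ranges[[fld]]
    if (length(rng) != 2L || rng[1] > rng[2])
      stop("range for ", fld, " must be c(min, max) with min <= max")
    mid <- vals[[fld]]
    if (!is.null(mid) && !is.na(mid) && (mid < rng[1] || mid > rng[2]))
      stop("mean of ", fld, " lies outside its declared range")
  }
  structure(c(list(name = name), vals, list(ranges = ranges)),
            class = "tissue_layer")
}

#' Composite single-layer membrane material
#'
#' Thickness-weighted aggregate of the abdominal tissue layers used as the
#' single-layer membrane material in the vibration model, or a silicone
#' phantom material with an explicit thickness.
#'
#' @param youngs_modulus Young's modulus \eqn{E} (Pa).
#' @param poisson_ratio Poisson's ratio \eqn{\mu}; must be < 0.5 so that the
#'   flexural rigidity \eqn{D = Eh^3/12(1-\mu^2)} stays finite.
#' @param density Density \eqn{\rho} (kg/m\eqn{^3}).
#' @param thickness Total membrane thickness \eqn{h} (m).
#'
#' @return An object of class `composite_membrane` with fields
#'   `youngs_modulus`, `poisson_ratio`, `density`, `thickness`.
#' @seealso [composite_properties()] to build one from [tissue_layer()]s.
#' @export
composite_membrane <- function(youngs_modulus, poisson_ratio, density,
                               thickness) {
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be > 0")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("composite poisson_ratio must be in [0, 0.5)")
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(thickness) || thickness <= 0) stop("thickness must be > 0")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 density = density, thickness = thickness),
            class = "composite_membrane")
}

#' Curved membrane geometry (design model of the gravid abdomen)
#'
#' Doubly curved rectangular membrane with clamped edges: side lengths
#' `side_a`, `side_b` along the surface and radii of curvature `radius_A`,
#' `radius_B`.
#'
#' @param side_a,side_b Side lengths (m).
#' @param radius_A,radius_B Radii of curvature (m).
#' @param thickness Membrane thickness (m).
#' @return An object of class `curved_geometry`.
#' @export
curved_geometry <- function(side_a, side_b, radius_A, radius_B, thickness) {
  v <- c(side_a, side_b, radius_A, radius_B, thickness)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all curved geometry dimensions must be positive")
  structure(list(side_a = side_a, side_b = side_b, radius_A = radius_A,
                 radius_B = radius_B, thickness = thickness),
            class = "curved_geometry")
}

#' Flat membrane geometry (silicone testbed)
#'
#' Flat rectangular membrane with clamped edges and an optional equal biaxial
#' prestress emulating the uterine wall tension.
#'
#' @param side_a,side_b Side lengths (m).
#' @param thickness Membrane thickness (m).
#' @param prestress Equal biaxial tensile stress \eqn{\sigma} (Pa), >= 0.
#' @return An object of class `flat_geometry`.
#' @export
flat_geometry <- function(side_a, side_b, thickness, prestress = 0) {
  v <- c(side_a, side_b, thickness)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("side lengths and thickness must be positive")
  if (!is.finite(prestress) || prestress < 0) stop("prestress must be >= 0")
  structure(list(side_a = side_a, side_b = side_b, thickness = thickness,
                 prestress = prestress),
            class = "flat_geometry")
}

#' @export
print.tissue_layer <- function(x, ...) {
  cat(sprintf("<tissue_layer> %s: E = %.4g kPa, mu = %.2f, h = %.3g mm, rho = %s\n",
              x$name, x$youngs_modulus / 1e3, x$poisson_ratio,
              x$thickness * 1e3,
              if (is.na(x$density)) "--" else sprintf("%.4g kg/m^3", x$density)))
  invisible(x)
}

#' @export
print.composite_membrane <- function(x, ...) {
  cat(sprintf(
    "<composite_membrane> E = %.4g kPa, mu = %.2f, rho = %.4g kg/m^3, h = %.3g mm\n",
    x$youngs_modulus / 1e3, x$poisson_ratio, x$density, x$thickness * 1e3))
  invisible(x)
}

# First vibration mode constant for a clamped square membrane (Galerkin
# solution); the only mode supported by the model.
#' Default mode constant for the flat-membrane frequency formula
#'
#' \eqn{\Lambda = 36.11^2}, the Galerkin constant for the first vibration mode
#' of a clamped square membrane. Rectangular (`a != b`) constants and higher
#' modes are out of scope.
#' @export
LAMBDA_SQUARE_MODE1 <- 36.11^2
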