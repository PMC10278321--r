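#' Fluid properties of (artificial) CSF
#'
#' Density and dynamic viscosity of the working fluid.  Defaults describe
#' cerebrospinal fluid: density 1.0006 g/ml and viscosity 1.002 mPa.s at
#' 20 degrees C (converted internally to cmH2O.s).
#'
#' @param density fluid density in g/ml.
#' @param viscosity dynamic viscosity in cmH2O.s.  Use
#'   [viscosity_cmh2o_s()] to convert from mPa.s, or pass
#'   [mu_csf_rounded] for the rounded 1e-5 cmH2O.s working value.
#' @return an object of class `fluid_properties` with fields `density`
#'   (g/ml) and `viscosity` (cmH2O.s).
#' @examples
#' fluid_properties()
#' fluid_properties(density = 1, viscosity = mu_csf_rounded)
#' @export
fluid_properties <- function(density = 1.0006,
                             viscosity = viscosity_cmh2o_s(1.002)) {
  check_positive(density, "density")
  check_positive(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Fluid: density %.4f g/ml, viscosity %.4g cmH2O.s\n",
              x$density, x$viscosity))
  invisible(x)
}

#' Spinal needle specification
#'
#' A needle is characterised hydraulically by its resistance to flow R
#' (cmH2O.s/ml).  R may be supplied directly (measured, e.g. by the
#' drop-weight method) or computed from length and internal diameter via
#' Poiseuille's law; at least one route must be available.  Outer diameter
#' is informational only (gauge does not determine the inner diameter).
#'
#' @param name needle label, e.g. `"22G Pajunk Sprotte"`.
#' @param gauge gauge label, e.g. `"22G"`.
#' @param length needle length in cm.
#' @param inner_diameter internal diameter in cm (optional).
#' @param outer_diameter external diameter in cm (optional, informational).
#' @param resistance measured resistance to flow in cmH2O.s/ml (optional).
#' @return an object of class `needle_spec`.
#' @seealso [needle_resistance()], [poiseuille_resistance()]
#' @export
needle_spec <- function(name, gauge = NA_character_, length,
                        inner_diameter = NULL, outer_diameter = NULL,
                        resistance = NULL) {
  check_positive(length, "length")
  if (is.null(inner_diameter) && is.null(resistance)) {
    stop_domain("needle_spec",
                "at least one of inner_diameter or resistance is required")
  }
  if (!is.null(inner_diameter)) check_positive(inner_diameter, "inner_diameter")
  if (!is.null(outer_diameter)) {
    check_positive(outer_diameter, "outer_diameter")
    if (!is.null(inner_diameter) && inner_diameter >= outer_diameter) {
      stop_domain("inner_diameter", "must be smaller than outer_diameter")
    }
  }
  if (!is.null(resistance)) check_positive(resistance, "resistance")
  structure(list(name = name, gauge = gauge, length = length,
                 inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 resistance = resistance),
            class = "needle_spec")
}

#' Resistance to flow of a needle
#'
#' Returns the measured resistance when present, otherwise the Poiseuille
#' value from geometry.
#'
#' @param needle a [needle_spec()].
#' @param fluid a [fluid_properties()]; only the viscosity is used, and only
#'   when falling back to geometry.
#' @return resistance in cmH2O.s/ml.
#' @export
needle_resistance <- function(needle, fluid = fluid_properties()) {
  if (!is.null(needle$resistance)) return(needle$resistance)
  poiseuille_resistance(needle$inner_diameter, needle$length, fluid$viscosity)
}

#' @export
print.needle_spec <- function(x, ...) {
  cat(sprintf("Spinal needle: %s (%s), length %.1f cm\n",
              x$name, x$gauge, x$length))
  if (!is.null(x$inner_diameter)) {
    cat(sprintf("  inner diameter: %.3f cm\n", x$inner_diameter))
  }
  if (!is.null(x$resistance)) {
    cat(sprintf("  measured resistance: %.1f cmH2O.s/ml\n", x$resistance))
  }
  invisible(x)
}

#' Spinal manometer specification
#'
#' The manometer is a graduated vertical tube; its bore diameter fixes the
#' inner cross-sectional area A = pi d^2 / 4 that converts accumulated
#' volume to column height.
#'
#' @param bore_diameter bore (internal) diameter in cm; the bench
#'   instrument modelled here has a 3.7 mm (0.37 cm) bore.
#' @return an object of class `manometer_spec` with fields `bore_diameter`
#'   (cm) and `area` (cm^2).
#' @examples
#' manometer_spec(0.37)$area   # 0.1075 cm^2
#' @export
manometer_spec <- function(bore_diameter = 0.37) {
  check_positive(bore_diameter, "bore_diameter")
  structure(list(bore_diameter = bore_diameter,
                 area = pi * bore_diameter^2 / 4),
            class = "manometer_spec")
}

#' @export
print.manometer_spec <- function(x, ...) {
  cat(sprintf("Manometer: bore %.2f mm, area %.5f cm^2\n",
              10 * x$bore_diameter, x$area))
  invisible(x)
}

#' Reservoir specification
#'
#' The constant-pressure reservoir feeding the needle.  A reservoir
#' diameter at least ten times the manometer bore keeps the pressure drop
#' from fluid lost into the manometer below 1% at equilibrium; see
#' [reservoir_pressure_drop_fraction()].
#'
#' @param diameter reservoir diameter in cm.
#' @param height reservoir fill height in cm (the reference pressure head).
#' @return an object of class `reservoir_spec`.
#' @export
reservoir_spec <- function(diameter, height = NA_real_) {
  check_positive(diameter, "diameter")
  structure(list(diameter = diameter, height = height),
            class = "reservoir_spec")
}

#' A drop-weight flow measurement
#'
#' One gravimetric measurement of flow through a needle: drops falling from
#' the open needle end are collected and weighed over a timed interval
#' under a known driving pressure.
#'
#' @param n_drops number of drops collected (integer).
#' @param total_mass total mass of collected fluid in g.
#' @param duration collection time in s.
#' @param applied_pressure driving pressure in cmH2O.
#' @return an object of class `drop_measurement`.
#' @seealso [flow_rate_from_drops()], [resistance_from_flow()]
#' @export
drop_measurement <- function(n_drops, total_mass, duration,
                             applied_pressure) {
  check_positive(n_drops, "n_drops")
  if (any(n_drops != round(n_drops))) {
    stop_domain("n_drops", "must be a whole number of drops")
  }
  check_positive(total_mass, "total_mass", allow_zero = TRUE)
  check_positive(duration, "duration")
  check_positive(applied_pressure, "applied_pressure")
  structure(list(n_drops = as.integer(n_drops), total_mass = total_mass,
                 duration = duration, applied_pressure = applied_pressure),
            class = "drop_measurement")
}

#' Needle-manometer assembly
#'
#' Combines a needle, a manometer and the working fluid into the
#' first-order measuring system.  The characteristic time constant
#' tau = R A / rho is derived on construction and revalidated on access, so
#' a stored assembly can never disagree with its components.
#'
#' @param needle a [needle_spec()].
#' @param manometer a [manometer_spec()].
#' @param fluid a [fluid_properties()].
#' @return an object of class `csf_assembly` with fields `needle`,
#'   `manometer`, `fluid`, `resistance` (cmH2O.s/ml) and `tau` (s).
#' @examples
#' nd <- needle_spec("22G Pajunk Sprotte", "22G", length = 9,
#'                   resistance = 667.9)
#' csf_assembly(nd, manometer_spec(0.37))
#' @export
csf_assembly <- function(needle, manometer = manometer_spec(),
                         fluid = fluid_properties()) {
  stopifnot(inherits(needle, "needle_spec"),
            inherits(manometer, "manometer_spec"),
            inherits(fluid, "fluid_properties"))
  R <- needle_resistance(needle, fluid)
  structure(list(needle = needle, manometer = manometer, fluid = fluid,
                 resistance = R,
                 tau = time_constant(R, manometer$area, fluid$density)),
            class = "csf_assembly")
}

#' @export
print.csf_assembly <- function(x, ...) {
  cat("Spinal needle-manometer assembly\n")
  cat(sprintf("  needle:     %s (R = %.1f cmH2O.s/ml)\n",
              x$needle$name, x$resistance))
  cat(sprintf("  manometer:  bore %.2f mm (A = %.5f cm^2)\n",
              10 * x$manometer$bore_diameter, x$manometer$area))
  cat(sprintf("  fluid:      rho = %.4f g/ml\n", x$fluid$density))
  cat(sprintf("  time constant tau = %.1f s (63%% of equilibrium at t = tau)\n",
              x$tau))
  invisible(x)
}
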