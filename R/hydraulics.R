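#' Poiseuille resistance to flow of a needle
#'
#' For laminar flow through a tube of internal diameter `d` and length `L`,
#' the volumetric flow under a pressure difference dP is
#' Q = dP * pi d^4 / (128 mu L), so the hydraulic resistance is
#' R = 128 mu L / (pi d^4).  R scales with the inverse fourth power of the
#' diameter: nominally identical gauges with slightly different bores have
#' very different resistances, which is why measured resistances are
#' preferred when available.
#'
#' @param d internal diameter in cm.
#' @param L needle length in cm.
#' @param mu dynamic viscosity in cmH2O.s (see [viscosity_cmh2o_s()]).
#' @return resistance to flow in cmH2O.s/ml.
#' @examples
#' poiseuille_resistance(d = 0.041, L = 8.8, mu = mu_csf_rounded)
#' @export
poiseuille_resistance <- function(d, L, mu) {
  check_positive(d, "d")
  check_positive(L, "L")
  check_positive(mu, "mu")
  128 * mu * L / (pi * d^4)
}

#' Flow rate from a drop-weight measurement
#'
#' Gravimetric flow estimate: total collected mass divided by density and
#' collection time, Q = m / (rho dt).
#'
#' @param measurement a [drop_measurement()].
#' @param fluid a [fluid_properties()].
#' @return flow rate in ml/s.
#' @examples
#' m <- drop_measurement(10, total_mass = 0.5736, duration = 25.5,
#'                       applied_pressure = 13)
#' flow_rate_from_drops(m)   # 0.0225 ml/s
#' @export
flow_rate_from_drops <- function(measurement, fluid = fluid_properties()) {
  stopifnot(inherits(measurement, "drop_measurement"))
  check_positive(measurement$duration, "duration")
  measurement$total_mass / (fluid$density * measurement$duration)
}

#' Resistance from pressure and flow
#'
#' R = dP / Q.  The driving pressure is an explicit argument: the bench
#' protocol nominally drives the needle at 13 cmH2O, but the product of the
#' tabulated resistances and flow rates implies closer to 15 cmH2O, so no
#' driving pressure is hard-coded (see the reproduction report, which shows
#' the back-calculated dP per measurement).
#'
#' @param delta_p driving pressure difference in cmH2O.
#' @param q flow rate in ml/s.
#' @return resistance in cmH2O.s/ml.
#' @export
resistance_from_flow <- function(delta_p, q) {
  if (!is.numeric(delta_p) || any(!is.finite(delta_p)) || any(delta_p < 0)) {
    stop_domain("delta_p", "must be finite and >= 0")
  }
  check_positive(q, "q")
  delta_p / q
}

#' Time constant of the needle-manometer assembly
#'
#' The assembly is a first-order system with characteristic time
#' tau = R A / rho: the column reaches 63% of its equilibrium height at
#' t = tau, 86% at 2 tau, 95% at 3 tau and 99% at 5 tau.
#'
#' @param R needle resistance to flow in cmH2O.s/ml.
#' @param A manometer cross-sectional area in cm^2.
#' @param rho fluid density in g/ml.
#' @return time constant in s.
#' @examples
#' time_constant(667.9, manometer_spec(0.37)$area)   # about 72 s
#' @export
time_constant <- function(R, A, rho = 1) {
  check_positive(R, "R")
  check_positive(A, "A")
  check_positive(rho, "rho")
  R * A / rho
}

#' Closed-form rise of the manometer column
#'
#' With constant CSF pressure the column height follows the exponential
#' saturation h(t) = (P_csf / rho) (1 - exp(-t / tau)), rising from a dry
#' manometer at t = 0 towards the equilibrium height P_csf / rho.
#'
#' @param t time in s (vectorised), t >= 0.
#' @param p_csf CSF pressure in cmH2O.
#' @param tau assembly time constant in s.
#' @param rho fluid density in g/ml.
#' @return column height in cm.
#' @examples
#' rise_height(c(0.693, 1, 2, 3, 5) * 72, p_csf = 13, tau = 72) / 13
#' @export
rise_height <- function(t, p_csf, tau, rho = 1) {
  if (any(t < 0)) stop_domain("t", "must be >= 0")
  check_positive(tau, "tau")
  check_positive(rho, "rho")
  (p_csf / rho) * (1 - exp(-t / tau))
}

#' Time to reach a fraction of the equilibrium pressure
#'
#' Inverts the rise curve: the time at which the column has covered a
#' fraction `r` of its equilibrium height is t = -tau log(1 - r),
#' independent of the CSF pressure itself.  This is the key practical
#' property of the first-order model: the clinician can read the column at
#' a known fraction of equilibrium and extrapolate, rather than waiting
#' about 5 tau for full equilibration (the wait for 99% is roughly 7 times
#' the wait for 50%).
#'
#' @param r target fraction of equilibrium in (0, 1) (vectorised).
#'   `r = 1` is rejected: equilibrium is only reached asymptotically.
#' @param tau assembly time constant in s.
#' @return time in s.
#' @examples
#' time_to_fraction(c(0.5, 0.63, 0.86, 0.95, 0.99), tau = 72)
#' @export
time_to_fraction <- function(r, tau) {
  if (any(r <= 0) || any(r >= 1)) stop_domain("r", "must lie strictly in (0, 1)")
  check_positive(tau, "tau")
  -tau * log(1 - r)
}

#' Extrapolate the equilibrium CSF pressure from an early reading
#'
#' Given a column height `h` read at a known time `t` after connecting the
#' manometer, the equilibrium CSF pressure follows by inverting the rise
#' curve: P_csf = rho h / (1 - exp(-t / tau)).  On a noiseless first-order
#' rise this recovers the true pressure at any t > 0; in practice early
#' readings amplify observation noise (the denominator is small), so
#' readings near or beyond t = tau are preferable.
#'
#' @param h observed column height in cm (vectorised with `t`).
#' @param t reading time in s, t > 0.
#' @param tau assembly time constant in s.
#' @param rho fluid density in g/ml.
#' @return extrapolated equilibrium CSF pressure in cmH2O.
#' @examples
#' extrapolate_equilibrium(h = 6.5, t = 49.9, tau = 72)   # about 13 cmH2O
#' @export
extrapolate_equilibrium <- function(h, t, tau, rho = 1) {
  check_positive(t, "t")
  check_positive(tau, "tau")
  check_positive(rho, "rho")
  if (any(h < 0)) stop_domain("h", "must be >= 0")
  rho * h / (1 - exp(-t / tau))
}

#' Low-pass cut-off frequency of the assembly
#'
#' The assembly acts as a first-order low-pass filter on the CSF pressure
#' with 3 dB cut-off f_c = 1 / (2 pi tau).  For typical time constants
#' (tens of seconds) f_c is a few mHz, far below respiratory (~0.3 Hz) and
#' cardiac (>1 Hz) pulsation frequencies, so the column reads the mean
#' pressure.
#'
#' @param tau assembly time constant in s.
#' @return cut-off frequency in Hz.
#' @examples
#' cutoff_frequency(50)   # 0.0032 Hz
#' @export
cutoff_frequency <- function(tau) {
  check_positive(tau, "tau")
  1 / (2 * pi * tau)
}

#' Normalised frequency-response gain
#'
#' Magnitude of the assembly's transfer function relative to its DC gain:
#' |H(f)| / |H(0)| = 1 / sqrt(1 + (2 pi f tau)^2).  Equals 1/sqrt(2)
#' (-3 dB) at the cut-off frequency.
#'
#' @param f frequency in Hz (vectorised), f >= 0.
#' @param tau assembly time constant in s.
#' @return dimensionless gain in (0, 1].
#' @examples
#' gain(0.3, tau = 50)    # respiratory rhythm: attenuated ~100-fold
#' @export
gain <- function(f, tau) {
  if (any(f < 0)) stop_domain("f", "must be >= 0")
  check_positive(tau, "tau")
  1 / sqrt(1 + (2 * pi * f * tau)^2)
}

#' Reservoir pressure-drop fraction at equilibrium
#'
#' The bench reservoir loses the volume that fills the manometer, so its
#' head drops by (A / A*) * h_eq where A and A* are the manometer and
#' reservoir cross-sections.  Expressed as a fraction of the reference
#' head `p0` this must stay small for the reservoir to approximate a
#' constant-pressure source; a reservoir diameter of at least ten times
#' the manometer bore keeps it below 1%.
#'
#' @param reservoir a [reservoir_spec()].
#' @param manometer a [manometer_spec()].
#' @param h_eq equilibrium column height in the manometer, cm.
#' @param p0 reference reservoir head in cm of fluid; defaults to `h_eq`
#'   (manometer equilibrates to the reservoir head).
#' @return dimensionless fractional pressure drop.
#' @examples
#' reservoir_pressure_drop_fraction(reservoir_spec(5), manometer_spec(0.37),
#'                                  h_eq = 13)   # 0.0055
#' @export
reservoir_pressure_drop_fraction <- function(reservoir, manometer, h_eq,
                                             p0 = h_eq) {
  stopifnot(inherits(reservoir, "reservoir_spec"),
            inherits(manometer, "manometer_spec"))
  check_positive(h_eq, "h_eq")
  check_positive(p0, "p0")
  check_positive(reservoir$diameter, "reservoir diameter")
  area_ratio <- (manometer$bore_diameter / reservoir$diameter)^2
  area_ratio * h_eq / p0
}
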