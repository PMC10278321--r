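#' Pulsatile CSF forcing
#'
#' The CSF pressure driving the assembly: a constant mean plus optional
#' cardiac and respiratory sinusoids.  At lumbar puncture the cardiac
#' component is about 0.1-0.2 cm of fluid above 1 Hz and the respiratory
#' one 0.2-0.5 cm (up to 1 cm with deep breathing) near 0.3 Hz; both sit
#' far above the assembly's mHz cut-off and are attenuated to invisibility
#' in the manometer.
#'
#' @param mean_pressure mean CSF pressure in cmH2O.
#' @param cardiac_amplitude,respiratory_amplitude sinusoid amplitudes in
#'   cm of fluid (0 disables the component).
#' @param cardiac_frequency,respiratory_frequency frequencies in Hz; must
#'   be positive when the matching amplitude is nonzero.
#' @return an object of class `pulsatile_forcing`; calling
#'   [forcing_pressure()] evaluates it at a vector of times.
#' @export
pulsatile_forcing <- function(mean_pressure,
                              cardiac_amplitude = 0,
                              cardiac_frequency = 1.2,
                              respiratory_amplitude = 0,
                              respiratory_frequency = 0.3) {
  check_positive(mean_pressure, "mean_pressure", allow_zero = TRUE)
  check_positive(cardiac_amplitude, "cardiac_amplitude", allow_zero = TRUE)
  check_positive(respiratory_amplitude, "respiratory_amplitude",
                 allow_zero = TRUE)
  if (cardiac_amplitude > 0) check_positive(cardiac_frequency,
                                            "cardiac_frequency")
  if (respiratory_amplitude > 0) check_positive(respiratory_frequency,
                                                "respiratory_frequency")
  structure(list(mean_pressure = mean_pressure,
                 cardiac_amplitude = cardiac_amplitude,
                 cardiac_frequency = cardiac_frequency,
                 respiratory_amplitude = respiratory_amplitude,
                 respiratory_frequency = respiratory_frequency),
            class = "pulsatile_forcing")
}

#' @rdname pulsatile_forcing
#' @param forcing a `pulsatile_forcing`.
#' @param t time(s) in s.
#' @export
forcing_pressure <- function(forcing, t) {
  forcing$mean_pressure +
    forcing$cardiac_amplitude *
      sin(2 * pi * forcing$cardiac_frequency * t) +
    forcing$respiratory_amplitude *
      sin(2 * pi * forcing$respiratory_frequency * t)
}

#' Simulation configuration
#'
#' @param time_step integration step in s; must not exceed tau/10 of the
#'   simulated assembly (enforced by [simulate_rise()]).
#' @param duration total simulated time in s.
#' @param observation_noise_sd Gaussian reading noise on crossing heights
#'   in cm (used by [generate_noisy_rise()]).
#' @param rng_seed integer seed for every stochastic path.
#' @param graduation_step manometer graduation spacing in cm.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(time_step = 0.05, duration = 600,
                              observation_noise_sd = 0, rng_seed = 1L,
                              graduation_step = 1) {
  check_positive(time_step, "time_step")
  check_positive(duration, "duration")
  if (duration <= time_step) {
    stop_domain("duration", "must exceed time_step")
  }
  check_positive(observation_noise_sd, "observation_noise_sd",
                 allow_zero = TRUE)
  check_positive(graduation_step, "graduation_step")
  structure(list(time_step = time_step, duration = duration,
                 observation_noise_sd = observation_noise_sd,
                 rng_seed = as.integer(rng_seed),
                 graduation_step = graduation_step),
            class = "simulation_config")
}

#' Integrate the manometer rise ODE
#'
#' Integrates the volume balance A dh/dt = (P(t) - rho h) / R from a dry
#' manometer h(0) = 0 with the classical fixed-step 4th-order Runge-Kutta
#' scheme.  With constant forcing the trajectory matches the closed-form
#' exponential rise; with pulsatile forcing the steady state carries a
#' ripple whose amplitude is the forcing amplitude times the low-pass
#' [gain()] at the forcing frequency.
#'
#' @param assembly a [csf_assembly()].
#' @param forcing a [pulsatile_forcing()] (or a bare number, taken as a
#'   constant pressure in cmH2O).
#' @param config a [simulation_config()]; `time_step` must be at most
#'   tau/10 (accuracy guard).
#' @return an object of class `simulated_trace`: a data frame with
#'   columns `time` (s) and `height` (cm), with the assembly, forcing and
#'   config attached as attributes.
#' @examples
#' nd <- needle_spec("22G Pajunk Sprotte", "22G", 9, resistance = 667.9)
#' asm <- csf_assembly(nd)
#' tr <- simulate_rise(asm, 13, simulation_config(0.05, 360))
#' @export
simulate_rise <- function(assembly, forcing, config = simulation_config()) {
  stopifnot(inherits(assembly, "csf_assembly"),
            inherits(config, "simulation_config"))
  if (is.numeric(forcing)) forcing <- pulsatile_forcing(forcing)
  tau <- assembly$tau
  if (config$time_step > tau / 10) {
    stop_domain("time_step",
                sprintf("must be <= tau/10 = %.3g s for accuracy", tau / 10))
  }
  RA <- assembly$resistance * assembly$manometer$area
  rho <- assembly$fluid$density
  dt <- config$time_step
  n <- floor(config$duration / dt)
  times <- seq(0, by = dt, length.out = n + 1)
  heights <- numeric(n + 1)
  deriv <- function(t, h) (forcing_pressure(forcing, t) - rho * h) / RA
  h <- 0
  for (i in seq_len(n)) {
    t0 <- times[i]
    k1 <- deriv(t0, h)
    k2 <- deriv(t0 + dt / 2, h + dt / 2 * k1)
    k3 <- deriv(t0 + dt / 2, h + dt / 2 * k2)
    k4 <- deriv(t0 + dt, h + dt * k3)
    h <- h + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    heights[i + 1] <- h
  }
  structure(data.frame(time = times, height = heights),
            assembly = assembly, forcing = forcing, config = config,
            class = c("simulated_trace", "data.frame"))
}

#' @export
print.simulated_trace <- function(x, ...) {
  a <- attr(x, "assembly")
  cat(sprintf(
    "Simulated rise: %s, tau = %.1f s, %d steps of %.3g s, final h = %.3f cm\n",
    a$needle$name, a$tau, nrow(x) - 1, attr(x, "config")$time_step,
    x$height[nrow(x)]))
  invisible(x)
}

#' Graduation crossing times of a trace
#'
#' Emulates the bench reading protocol: for each graduation k * step up to
#' `max_height`, the first time the trace reaches that height, linearly
#' interpolated between integration steps.  Graduations the trace never
#' reaches are omitted (reported via a warning), not fabricated.
#'
#' @param trace a [simulate_rise()] result (or any data frame with `time`
#'   and `height` columns).
#' @param graduation_step graduation spacing in cm.
#' @param max_height last graduation to read, cm.
#' @param needle,replicate labels for the resulting dataset.
#' @return a [rise_dataset()].
#' @export
crossing_times <- function(trace, graduation_step = 1, max_height,
                           needle = "simulated", replicate = "M1") {
  check_positive(graduation_step, "graduation_step")
  check_positive(max_height, "max_height")
  marks <- seq(graduation_step, max_height, by = graduation_step)
  tt <- trace$time
  hh <- trace$height
  cross <- vapply(marks, function(m) {
    i <- which(hh >= m)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(tt[1])
    # linear interpolation of first passage within the bracketing step
    tt[i - 1] + (tt[i] - tt[i - 1]) * (m - hh[i - 1]) / (hh[i] - hh[i - 1])
  }, numeric(1))
  reached <- !is.na(cross)
  if (!all(reached)) {
    warning(sprintf("graduations above %.3g cm not reached within %.3g s",
                    max(marks[reached], 0), max(tt)), call. = FALSE)
  }
  rise_dataset(cross[reached], marks[reached],
               needle = needle, replicate = replicate)
}

#' Generate seeded noisy rise datasets
#'
#' Fixture generator for the estimator: the closed-form rise curve of the
#' assembly is read at each graduation (exact inverse crossing times) and
#' Gaussian reading noise of sd `observation_noise_sd` is added to the
#' recorded heights.  Deterministic given `rng_seed`; with zero noise it
#' reduces to the crossing times of the closed form.
#'
#' @param assembly a [csf_assembly()].
#' @param p_csf CSF pressure in cmH2O.
#' @param config a [simulation_config()]; `graduation_step`, `duration`
#'   and `observation_noise_sd` are used.
#' @param n_replicates number of replicate datasets.
#' @return a list of `n_replicates` [rise_dataset()] objects (heights
#'   noisy, monotonicity not enforced: returned as plain data frames when
#'   noise breaks it).
#' @export
generate_noisy_rise <- function(assembly, p_csf,
                                config = simulation_config(),
                                n_replicates = 1) {
  stopifnot(inherits(assembly, "csf_assembly"))
  check_positive(p_csf, "p_csf")
  tau <- assembly$tau
  rho <- assembly$fluid$density
  h_eq <- p_csf / rho
  marks <- seq(config$graduation_step, h_eq - config$graduation_step / 2,
               by = config$graduation_step)
  t_cross <- time_to_fraction(marks / h_eq, tau)
  keep <- t_cross <= config$duration
  marks <- marks[keep]
  t_cross <- t_cross[keep]
  set.seed(config$rng_seed)
  lapply(seq_len(n_replicates), function(i) {
    hh <- marks
    if (config$observation_noise_sd > 0) {
      hh <- hh + stats::rnorm(length(marks),
                              sd = config$observation_noise_sd)
    }
    d <- data.frame(time = t_cross, height = pmax(hh, 0))
    if (all(diff(d$height) >= 0)) {
      d <- rise_dataset(d$time, d$height, needle = attr_name(assembly),
                        replicate = paste0("S", i))
    }
    d
  })
}

attr_name <- function(assembly) assembly$needle$name

#' Write a simulated trace and its metadata
#'
#' The trace goes to CSV (`time_s,height_cm`); assembly, forcing and
#' config metadata (including the seed) go to a plain-text sidecar
#' `<path>.meta` in `key: value` form.
#'
#' @param trace a [simulate_rise()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time, height_cm = trace$height),
                   path, row.names = FALSE, quote = FALSE)
  a <- attr(trace, "assembly")
  f <- attr(trace, "forcing")
  cfg <- attr(trace, "config")
  meta <- c(
    sprintf("needle: %s", a$needle$name),
    sprintf("resistance_cm_s_per_ml: %.6g", a$resistance),
    sprintf("bore_diameter_cm: %.6g", a$manometer$bore_diameter),
    sprintf("density_g_per_ml: %.6g", a$fluid$density),
    sprintf("tau_s: %.6g", a$tau),
    sprintf("mean_pressure_cmH2O: %.6g", f$mean_pressure),
    sprintf("cardiac_amplitude_cm: %.6g", f$cardiac_amplitude),
    sprintf("cardiac_frequency_hz: %.6g", f$cardiac_frequency),
    sprintf("respiratory_amplitude_cm: %.6g", f$respiratory_amplitude),
    sprintf("respiratory_frequency_hz: %.6g", f$respiratory_frequency),
    sprintf("time_step_s: %.6g", cfg$time_step),
    sprintf("duration_s: %.6g", cfg$duration),
    sprintf("rng_seed: %d", cfg$rng_seed)
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
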