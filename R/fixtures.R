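extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "csfmanometry")
  if (p == "") stop("bundled fixture ", file, " not found", call. = FALSE)
  p
}

# frozen content checks for the bundled tables: row counts plus column sums
# (3 decimals).  A transcription edit that changes any value trips these.
fixture_checks <- list(
  table1 = list(n = 9L, mass_sum = 4879.4, r_sum = 9323.8),
  table2 = list(n = 117L, time_sum = 15177.299),
  table3 = list(n = 5L, r_sum = 6473.76, tau_sum = 328.7)
)

#' Load a bundled bench-data fixture
#'
#' Three plain-text tables of bench measurements ship with the package
#' (decimal commas in the source normalised to points; the raw
#' transcription is at `extdata/table2_raw.txt`):
#' \describe{
#'   \item{`table1`}{drop-weight resistance measurements for three 22G
#'     spinal needles, three replicates each: drop counts, total drop mass
#'     (returned in g), collection time, and the flow rate and resistance
#'     as originally reported.}
#'   \item{`table2`}{manometer rise readings (1 cm graduations up to
#'     13 cm) for the same needles under a 13 cmH2O head, three replicates
#'     each, as a list of nine [rise_dataset()] objects.}
#'   \item{`table3`}{published (resistance, time constant) pairs for five
#'     spinal needle types on a common manometer, for the tau-vs-R
#'     regression.}
#' }
#' Each load revalidates the bundled content against frozen row counts and
#' column sums and fails loudly on mismatch.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return see Details; `table1` and `table3` are data frames, `table2` a
#'   named list of [rise_dataset()]s.
#' @examples
#' head(load_fixture("table1"))
#' names(load_fixture("table2"))
#' @export
load_fixture <- function(name) {
  if (!name %in% names(fixture_checks)) {
    stop("unknown fixture: ", name,
         " (expected table1, table2 or table3)", call. = FALSE)
  }
  chk <- fixture_checks[[name]]
  bad <- function() stop("bundled fixture ", name,
                         " failed its content check", call. = FALSE)
  if (name == "table1") {
    d <- utils::read.csv(extdata_path("table1.csv"))
    if (nrow(d) != chk$n ||
        round(sum(d$total_mass_mg), 3) != chk$mass_sum ||
        round(sum(d$R_cm_s_per_ml), 3) != chk$r_sum) bad()
    d$total_mass_g <- d$total_mass_mg / 1000
    d
  } else if (name == "table2") {
    sets <- read_rise_csv(extdata_path("table2.csv"))
    n <- sum(vapply(sets, nrow, integer(1)))
    tsum <- round(sum(unlist(lapply(sets, `[[`, "time"))), 3)
    if (n != chk$n || tsum != chk$time_sum) bad()
    sets
  } else {
    d <- read_tau_resistance_csv(extdata_path("table3.csv"))
    if (nrow(d) != chk$n || round(sum(d$R), 3) != chk$r_sum ||
        round(sum(d$tau), 3) != chk$tau_sum) bad()
    d
  }
}

#' End-to-end reproduction of the bundled bench analyses
#'
#' Chains the whole pipeline on the bundled fixtures: gravimetric flow
#' rates and resistances from the drop-weight table, time constants for
#' the 3.7 mm-bore manometer, equilibration-time averages and exponential
#' fits for the rise data, RMS validation errors under both protocols
#' (theoretical tau from resistance, and fitted tau), and the tau-vs-R
#' regression over the published pairs.
#'
#' The driving pressure for resistance computation is an explicit
#' argument because the bundled data are ambiguous about it: the bench
#' protocol states 13 cmH2O, but the product of each tabulated resistance
#' and flow rate implies about 15 cmH2O.  The report computes resistances
#' at `delta_p` and also shows the back-calculated driving pressure
#' `R_reported * Q_reported` per measurement, so the discrepancy is
#' visible rather than hidden.
#'
#' @param delta_p driving pressure in cmH2O used to recompute resistances
#'   from flow rates.
#' @param fluid a [fluid_properties()].
#' @param bore_diameter manometer bore in cm.
#' @return an object of class `reproduction_report`; print it, or write
#'   it with [write_reproduction_report()].
#' @examples
#' rep <- run_reproduction()
#' rep$time_constants
#' @export
run_reproduction <- function(delta_p = 13, fluid = fluid_properties(),
                             bore_diameter = 0.37) {
  check_positive(delta_p, "delta_p")
  man <- manometer_spec(bore_diameter)
  t1 <- load_fixture("table1")
  q <- vapply(seq_len(nrow(t1)), function(i) {
    flow_rate_from_drops(
      drop_measurement(t1$n_drops[i], t1$total_mass_g[i], t1$duration_s[i],
                       delta_p), fluid)
  }, numeric(1))
  flows <- data.frame(
    needle = t1$needle, replicate = t1$replicate,
    flow_ml_per_s = round(q, 4),
    flow_reported = t1$flow_rate_ml_per_s,
    R_at_delta_p = round(resistance_from_flow(delta_p, q), 1),
    R_reported = t1$R_cm_s_per_ml,
    delta_p_back_calculated = round(t1$R_cm_s_per_ml *
                                      t1$flow_rate_ml_per_s, 2))

  needles <- unique(t1$needle)
  r_mean <- tapply(t1$R_cm_s_per_ml, factor(t1$needle, levels = needles),
                   mean)
  r_sd <- tapply(t1$R_cm_s_per_ml, factor(t1$needle, levels = needles),
                 stats::sd)
  taus <- data.frame(
    needle = needles,
    R_mean = round(as.vector(r_mean), 1),
    R_sd = round(as.vector(r_sd), 2),
    tau_s = as.vector(r_mean) * man$area / fluid$density,
    row.names = NULL)
  taus$tau_rounded_s <- round(taus$tau_s)

  t2 <- load_fixture("table2")
  equil <- equilibration_time_summary(t2, final_height = 13)

  fits <- lapply(t2, fit_rise, fluid = fluid)
  fit_tab <- data.frame(
    needle = vapply(t2, attr, character(1), "needle"),
    replicate = vapply(t2, attr, character(1), "replicate"),
    p_inf = vapply(fits, function(f) f$coefficients[["p_inf"]], numeric(1)),
    tau = vapply(fits, function(f) f$coefficients[["tau"]], numeric(1)),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    n = vapply(t2, nrow, integer(1)),
    row.names = NULL)

  rms <- do.call(rbind, lapply(seq_along(needles), function(i) {
    nd <- needles[i]
    sets <- t2[fit_tab$needle == nd]
    tau_theor <- taus$tau_s[i]
    pooled <- fit_rise(do.call(rbind, lapply(sets, as.data.frame)),
                       fluid = fluid)
    data.frame(
      needle = nd,
      rms_theoretical_tau = rms_error(sets, p_inf = 13, tau = tau_theor,
                                      rho = fluid$density),
      rms_fitted_tau = rms_error(sets,
                                 p_inf = pooled$coefficients[["p_inf"]],
                                 tau = pooled$coefficients[["tau"]],
                                 rho = fluid$density))
  }))

  reg <- tau_r_regression(load_fixture("table3"))

  structure(list(delta_p = delta_p, fluid = fluid, manometer = man,
                 flows = flows, time_constants = taus,
                 equilibration = equil, fits = fit_tab, rms = rms,
                 regression = reg),
            class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Bench reproduction report (needle-manometer first-order model)\n")
  cat(sprintf("  manometer bore %.2f mm (A = %.5f cm^2); rho = %.4f g/ml\n",
              10 * x$manometer$bore_diameter, x$manometer$area,
              x$fluid$density))
  cat(sprintf("\nFlow rates (ml/s) and resistances at delta_p = %g cmH2O;\n",
              x$delta_p))
  cat("reported resistances imply the back-calculated delta_p column:\n")
  print(x$flows, row.names = FALSE)
  cat("\nTime constants tau = R*A/rho (s), from reported mean resistances:\n")
  print(x$time_constants, row.names = FALSE)
  cat("\nMean equilibration times to 13 cm (s):\n")
  print(transform(x$equilibration, mean_time = round(mean_time, 1)),
        row.names = FALSE)
  cat("\nExponential fits per replicate (p_inf cmH2O, tau s):\n")
  print(transform(x$fits, p_inf = round(p_inf, 2), tau = round(tau, 1),
                  r_squared = round(r_squared, 4)), row.names = FALSE)
  cat("\nRMS validation error (cmH2O), both protocols:\n")
  print(transform(x$rms, rms_theoretical_tau = round(rms_theoretical_tau, 2),
                  rms_fitted_tau = round(rms_fitted_tau, 2)),
        row.names = FALSE)
  cat("\n")
  print(x$regression)
  invisible(x)
}

#' Write a reproduction report to disk
#'
#' Emits the human-readable text log plus one CSV per report table.
#'
#' @param report a [run_reproduction()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reproduction_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  for (nm in c("flows", "time_constants", "equilibration", "fits", "rms")) {
    utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  reg <- report$regression
  utils::write.csv(data.frame(slope_cm2 = reg$slope, intercept_s = reg$intercept,
                              r_squared = reg$r_squared,
                              implied_bore_mm = 10 * reg$implied_bore_diameter),
                   file.path(dir, "regression.csv"), row.names = FALSE)
  invisible(dir)
}
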