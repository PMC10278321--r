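#' Fit the first-order rise curve to manometer observations
#'
#' Least-squares fit of the exponential saturation
#' h(t) = h_inf (1 - exp(-t / tau)) to observed graduation-crossing data,
#' the bench verification step of the first-order needle-manometer model.
#' The equilibrium column height h_inf is reported as the equilibrium CSF
#' pressure `p_inf = rho * h_inf` in cmH2O.
#'
#' The joint fit is computed by variable projection: for any trial tau the
#' optimal amplitude is the closed-form linear least-squares solution
#' `h_inf(tau) = sum(g h) / sum(g^2)` with `g = 1 - exp(-t/tau)`, so only
#' tau requires numerical search.  The profiled sum of squares is
#' minimised by golden-section/parabolic search started from the
#' 63%-of-maximum anchor (the time at which a first-order system crosses
#' 63% of equilibrium is tau itself), then polished by Gauss-Newton steps
#' until the relative change in the residual sum of squares falls below
#' `1e-10` or 500 iterations elapse; failure to converge is an error
#' carrying the best iterate, not a silent return.
#'
#' @param data a [rise_dataset()], or anything coercible via
#'   `rise_dataset()` when given a two-column `time`/`height` data frame.
#' @param mode `"joint"` fits both parameters (needs >= 3 observations);
#'   `"fixed_tau"` takes tau as known and solves the amplitude in closed
#'   form; `"fixed_p"` takes the equilibrium pressure as known and fits
#'   only tau.
#' @param fluid a [fluid_properties()]; the density converts the fitted
#'   equilibrium height (cm) to pressure (cmH2O).
#' @param fixed_value the known parameter for the single-parameter modes:
#'   tau in s for `"fixed_tau"`, equilibrium pressure in cmH2O for
#'   `"fixed_p"`.
#' @param control list of optional overrides: `max_iter` (default 500) and
#'   `ssr_tol` (default 1e-10), the Gauss-Newton budget and relative-SSR
#'   convergence tolerance.
#' @return an object of class `rise_fit`: a list with components
#'   `coefficients` (named vector `p_inf` in cmH2O, `tau` in s),
#'   `r_squared`, `rmse` (cmH2O), `residuals`, `fitted.values`, `data`,
#'   `mode`, `fluid`, `iterations` and `converged`.
#' @examples
#' d <- rise_dataset(time = -72 * log(1 - (1:12) / 13),
#'                   height = 1:12)
#' fit <- fit_rise(d)
#' coef(fit)
#' summary(fit)
#' @seealso [rms_error()], [times_to_percentages()], [predict.rise_fit()]
#' @export
fit_rise <- function(data, mode = c("joint", "fixed_tau", "fixed_p"),
                     fluid = fluid_properties(), fixed_value = NULL,
                     control = list()) {
  mode <- match.arg(mode)
  if (!inherits(data, "rise_dataset")) {
    # any (time, height) pairs are fittable: pooled replicates and noisy
    # observations need not satisfy the monotone reading-protocol invariants
    if (!all(c("time", "height") %in% names(data))) {
      stop_domain("data", "must have time and height columns")
    }
    ord <- order(data$time)
    data <- data.frame(time = as.numeric(data$time[ord]),
                       height = as.numeric(data$height[ord]))
    if (any(data$time < 0)) stop_domain("time", "must be >= 0")
  }
  ctl <- list(max_iter = 500, ssr_tol = 1e-10)
  ctl[names(control)] <- control
  t <- data$time
  h <- data$height
  n <- length(t)
  if (mode == "joint" && n < 3) {
    stop_estimation("joint fit requires at least 3 observations", NULL)
  }
  if (n < 1) stop_estimation("no observations", NULL)
  if (mode != "joint" && is.null(fixed_value)) {
    stop_domain("fixed_value", paste("required for mode", mode))
  }
  if (stats::var(h) == 0 && mode == "joint") {
    stop_estimation("degenerate data: all heights equal", NULL)
  }

  rho <- fluid$density
  profile_hinf <- function(tau) {
    g <- 1 - exp(-t / tau)
    sum(g * h) / sum(g * g)
  }
  ssr_at <- function(hinf, tau) sum((h - hinf * (1 - exp(-t / tau)))^2)

  if (mode == "fixed_tau") {
    tau <- fixed_value
    check_positive(tau, "fixed_value (tau)")
    hinf <- profile_hinf(tau)
    iters <- 0L
    converged <- TRUE
  } else {
    tau0 <- init_tau(t, h)
    profile_ssr <- function(tau) ssr_at(profile_hinf(tau), tau)
    if (mode == "fixed_p") {
      check_positive(fixed_value, "fixed_value (p_inf)")
      hinf_fixed <- fixed_value / rho
      profile_ssr <- function(tau) ssr_at(hinf_fixed, tau)
    }
    opt <- stats::optimize(profile_ssr, c(tau0 / 100, tau0 * 100),
                           tol = .Machine$double.eps^0.5)
    tau <- opt$minimum
    hinf <- if (mode == "fixed_p") fixed_value / rho else profile_hinf(tau)
    gn <- gauss_newton_polish(t, h, hinf, tau,
                              fix_hinf = (mode == "fixed_p"),
                              max_iter = ctl$max_iter, tol = ctl$ssr_tol)
    hinf <- gn$hinf
    tau <- gn$tau
    iters <- gn$iterations
    converged <- gn$converged
    if (!converged) {
      stop_estimation(
        sprintf("fit did not converge in %d iterations", ctl$max_iter),
        best = list(p_inf = rho * hinf, tau = tau, ssr = gn$ssr))
    }
  }

  fitted <- hinf * (1 - exp(-t / tau))
  res <- h - fitted
  ssr <- sum(res^2)
  sst <- sum((h - mean(h))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  structure(list(
    coefficients = c(p_inf = rho * unname(hinf), tau = unname(tau)),
    r_squared = r2,
    rmse = sqrt(mean(res^2)),
    residuals = res,
    fitted.values = fitted,
    data = data,
    mode = mode,
    fluid = fluid,
    iterations = iters,
    converged = converged,
    call = match.call()
  ), class = "rise_fit")
}

# 63% anchor: interpolated time of first crossing of 0.63 * max(h)
# (robust to non-monotone noisy heights: first passage is used).
init_tau <- function(t, h) {
  target <- 0.63 * max(h)
  i <- which(h >= target)[1]
  if (i == 1) return(max(t[1], .Machine$double.eps))
  if (h[i] == h[i - 1]) return(t[i])
  t[i - 1] + (t[i] - t[i - 1]) * (target - h[i - 1]) / (h[i] - h[i - 1])
}

# Gauss-Newton refinement of (hinf, tau) (or tau alone), step-halved so the
# SSR never increases; converged when the relative SSR change is < tol.
gauss_newton_polish <- function(t, h, hinf, tau, fix_hinf, max_iter, tol) {
  ssr_at <- function(hinf, tau) sum((h - hinf * (1 - exp(-t / tau)))^2)
  ssr <- ssr_at(hinf, tau)
  for (iter in seq_len(max_iter)) {
    e <- exp(-t / tau)
    g <- 1 - e
    r <- h - hinf * g
    d_tau <- -hinf * t * e / tau^2           # d fitted / d tau
    J <- if (fix_hinf) cbind(d_tau) else cbind(g, d_tau)
    step <- tryCatch(qr.solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      if (fix_hinf) {
        tau_new <- tau + lambda * step[1]
        hinf_new <- hinf
      } else {
        hinf_new <- hinf + lambda * step[1]
        tau_new <- tau + lambda * step[2]
      }
      if (tau_new > 0 && (ssr_new <- ssr_at(hinf_new, tau_new)) <= ssr) break
      lambda <- lambda / 2
      if (lambda < 1e-8) {
        hinf_new <- hinf; tau_new <- tau; ssr_new <- ssr
        break
      }
    }
    done <- (ssr - ssr_new) <= tol * max(ssr, .Machine$double.xmin)
    hinf <- hinf_new; tau <- tau_new; ssr <- ssr_new
    if (done) {
      return(list(hinf = hinf, tau = tau, ssr = ssr, iterations = iter,
                  converged = TRUE))
    }
  }
  list(hinf = hinf, tau = tau, ssr = ssr, iterations = max_iter,
       converged = FALSE)
}

stop_estimation <- function(msg, best) {
  cond <- structure(class = c("csf_estimation_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1), best = best))
  stop(cond)
}

#' @export
print.rise_fit <- function(x, digits = 4, ...) {
  cat("First-order manometer rise fit (mode:", x$mode, ")\n")
  cat(sprintf("  equilibrium pressure P_inf = %.*g cmH2O\n", digits,
              x$coefficients[["p_inf"]]))
  cat(sprintf("  time constant      tau    = %.*g s\n", digits,
              x$coefficients[["tau"]]))
  cat(sprintf("  R-squared = %.4f, RMSE = %.*g cmH2O (n = %d)\n",
              x$r_squared, digits, x$rmse, nrow(x$data)))
  invisible(x)
}

#' @export
coef.rise_fit <- function(object, ...) object$coefficients

#' @export
residuals.rise_fit <- function(object, ...) object$residuals

#' @export
fitted.rise_fit <- function(object, ...) object$fitted.values

#' Predict column heights from a fitted rise curve
#'
#' @param object a [fit_rise()] result.
#' @param newdata optional vector of times in s, or a data frame with a
#'   `time` column; defaults to the times the model was fitted to.
#' @param ... unused.
#' @return predicted heights in cm.
#' @export
predict.rise_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  t <- if (is.data.frame(newdata)) newdata$time else newdata
  rise_height(t, object$coefficients[["p_inf"]],
              object$coefficients[["tau"]], object$fluid$density)
}

#' @export
summary.rise_fit <- function(object, ...) {
  out <- object
  out$time_to_63 <- time_to_fraction(0.63, object$coefficients[["tau"]])
  out$time_to_99 <- time_to_fraction(0.99, object$coefficients[["tau"]])
  class(out) <- "summary.rise_fit"
  out
}

#' @export
print.summary.rise_fit <- function(x, ...) {
  print.rise_fit(x, ...)
  cat(sprintf("  63%% of equilibrium at %.1f s; 99%% at %.1f s\n",
              x$time_to_63, x$time_to_99))
  cat("  residuals (cm):\n")
  print(summary(x$residuals))
  invisible(x)
}

#' @export
plot.rise_fit <- function(x, ...) {
  d <- x$data
  tt <- seq(0, max(d$time) * 1.05, length.out = 200)
  graphics::plot(d$time, d$height, xlab = "time (s)",
                 ylab = "column height (cm)",
                 main = sprintf("%s: P = %.1f cmH2O, tau = %.1f s",
                                attr(d, "needle"),
                                x$coefficients[["p_inf"]],
                                x$coefficients[["tau"]]), ...)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Simulate replicate datasets from a fitted rise curve
#'
#' Draws new observations at the fitted time points with i.i.d. Gaussian
#' noise of standard deviation equal to the fit RMSE (parametric bootstrap
#' of the reading protocol).
#'
#' @param object a [fit_rise()] result.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed for reproducibility.
#' @param ... unused.
#' @return a list of `nsim` [rise_dataset()]-shaped data frames (heights
#'   are noisy, so monotonicity is not enforced).
#' @export
simulate.rise_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  t <- object$data$time
  mu <- object$fitted.values
  lapply(seq_len(nsim), function(i) {
    data.frame(time = t, height = pmax(0, mu + stats::rnorm(length(t),
                                                            sd = object$rmse)))
  })
}

#' Root-mean-square error of a rise curve against observations
#'
#' Evaluates h(t) = (p_inf / rho)(1 - exp(-t / tau)) at the observation
#' times and returns the RMS height residual.  The (p_inf, tau) pair is
#' explicit so the same call serves both validation protocols: a
#' theoretical curve (tau from resistance and bore area) or a fitted one.
#'
#' @param data a [rise_dataset()] or a list of them (pooled).
#' @param p_inf equilibrium pressure in cmH2O.
#' @param tau time constant in s.
#' @param rho fluid density in g/ml.
#' @return RMS error in cmH2O (cm of fluid).
#' @export
rms_error <- function(data, p_inf, tau, rho = 1) {
  check_positive(tau, "tau")
  if (inherits(data, "rise_dataset")) data <- list(data)
  t <- unlist(lapply(data, `[[`, "time"))
  h <- unlist(lapply(data, `[[`, "height"))
  if (length(t) == 0) stop_domain("data", "contains no observations")
  sqrt(mean((h - rise_height(t, p_inf, tau, rho))^2))
}

#' Mean equilibration time per needle
#'
#' The bench equilibration time of a replicate is the recorded time at
#' which the column reached the final height.  Replicates are grouped by
#' their needle label and averaged.
#'
#' @param datasets a list of [rise_dataset()] objects.
#' @param final_height the equilibrium height in cm (the reading protocol
#'   stops here); every replicate must contain an observation at it.
#' @return a data frame with columns `needle`, `n_replicates`,
#'   `mean_time` (s).
#' @examples
#' # with the bundled bench data:
#' eq <- equilibration_time_summary(load_fixture("table2"), 13)
#' @export
equilibration_time_summary <- function(datasets, final_height) {
  check_positive(final_height, "final_height")
  times <- vapply(datasets, function(d) {
    i <- which(abs(d$height - final_height) < 1e-9)
    if (length(i) == 0) {
      stop(sprintf("replicate %s/%s has no observation at height %g cm",
                   attr(d, "needle"), attr(d, "replicate"), final_height),
           call. = FALSE)
    }
    d$time[i[1]]
  }, numeric(1))
  needles <- vapply(datasets, attr, character(1), "needle")
  agg <- tapply(times, factor(needles, levels = unique(needles)), mean)
  data.frame(needle = names(agg),
             n_replicates = as.vector(table(factor(needles,
                                                   levels = names(agg)))),
             mean_time = as.vector(agg), row.names = NULL)
}

#' Times to reach given percentages of equilibrium
#'
#' Applies the inverse rise curve at the fitted (or supplied) time
#' constant for each requested percentage of the equilibrium pressure.
#'
#' @param fit a [fit_rise()] result, or a bare time constant in s.
#' @param percentages percentages of equilibrium in (0, 100).
#' @return named numeric vector of times in s.
#' @examples
#' times_to_percentages(60, c(33.3, 50, 66.7, 83.3, 91.7, 95.8))
#' @export
times_to_percentages <- function(fit, percentages) {
  tau <- if (inherits(fit, "rise_fit")) fit$coefficients[["tau"]] else fit
  if (any(percentages <= 0) || any(percentages >= 100)) {
    stop_domain("percentages", "must lie strictly in (0, 100)")
  }
  out <- time_to_fraction(percentages / 100, tau)
  names(out) <- paste0(format(percentages, trim = TRUE), "%")
  out
}

#' Regression of time constant on resistance to flow
#'
#' Ordinary least squares of tau (s) on R (cmH2O.s/ml) across needles
#' measured with a common manometer.  Under the first-order model
#' tau = (A / rho) R, so the slope estimates the manometer cross-sectional
#' area (cm^2, for rho ~ 1) and the implied bore diameter
#' d = sqrt(4 * slope / pi) can be checked against the physical
#' instrument.
#'
#' @param pairs a data frame with numeric columns `R` and `tau` (as from
#'   [read_tau_resistance_csv()]); at least two distinct `R` values.
#' @return an object of class `tau_r_fit` with components `slope` (cm^2),
#'   `intercept` (s), `r_squared`, `implied_bore_diameter` (cm) and the
#'   underlying `lm` fit.
#' @examples
#' tau_r_regression(load_fixture("table3"))
#' @export
tau_r_regression <- function(pairs) {
  if (!all(c("R", "tau") %in% names(pairs))) {
    stop_domain("pairs", "must have columns R and tau")
  }
  if (nrow(pairs) < 2 || length(unique(pairs$R)) < 2) {
    stop_domain("pairs", "needs at least two distinct R values")
  }
  fit <- stats::lm(tau ~ R, data = pairs)
  slope <- unname(stats::coef(fit)[["R"]])
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = summary(fit)$r.squared,
    implied_bore_diameter = if (slope > 0) sqrt(4 * slope / pi) else NA_real_,
    lm = fit
  ), class = "tau_r_fit")
}

#' @export
print.tau_r_fit <- function(x, ...) {
  cat(sprintf("tau-vs-R regression: tau = %.3f * R %+.2f  (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  if (!is.na(x$implied_bore_diameter)) {
    cat(sprintf("  slope as manometer area implies bore %.2f mm\n",
                10 * x$implied_bore_diameter))
  }
  invisible(x)
}

#' @export
coef.tau_r_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
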