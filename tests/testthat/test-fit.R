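test_that("joint fit recovers noiseless parameters across the regime", {
  for (tau in c(10, 72, 150, 300)) {
    for (p in c(5, 13, 24, 40)) {
      d <- closed_form_dataset(p = p, tau = tau, heights = (1:12) / 12 * p * 0.92)
      f <- fit_rise(d, fluid = fluid_properties(density = 1))
      expect_equal(unname(coef(f)[["p_inf"]]), p, tolerance = 1e-6)
      expect_equal(unname(coef(f)[["tau"]]), tau, tolerance = 1e-6)
      expect_true(f$converged)
      expect_equal(f$r_squared, 1, tolerance = 1e-10)
    }
  }
})

test_that("joint fit agrees with an independent nls fit on noisy data", {
  set.seed(42)
  tau <- 90; p <- 15
  tt <- seq(2, 400, by = 8)
  hh <- rise_height(tt, p, tau) + rnorm(length(tt), sd = 0.15)
  d <- data.frame(time = tt, height = pmax(hh, 0))
  ours <- fit_rise(d, fluid = fluid_properties(density = 1))
  oracle <- nls(height ~ P * (1 - exp(-time / tau)), data = d,
                start = list(P = max(d$height), tau = 60))
  expect_equal(unname(coef(ours)[["p_inf"]]), unname(coef(oracle)[["P"]]),
               tolerance = 1e-5)
  expect_equal(unname(coef(ours)[["tau"]]), unname(coef(oracle)[["tau"]]),
               tolerance = 1e-5)
  expect_equal(sum(residuals(ours)^2), sum(residuals(oracle)^2),
               tolerance = 1e-8)
})

test_that("single-parameter modes recover the free parameter exactly", {
  d <- closed_form_dataset(p = 24, tau = 111)
  ft <- fit_rise(d, mode = "fixed_tau", fixed_value = 111,
                 fluid = fluid_properties(density = 1))
  expect_equal(unname(coef(ft)[["p_inf"]]), 24, tolerance = 1e-10)
  fp <- fit_rise(d, mode = "fixed_p", fixed_value = 24,
                 fluid = fluid_properties(density = 1))
  expect_equal(unname(coef(fp)[["tau"]]), 111, tolerance = 1e-6)
  expect_error(fit_rise(d, mode = "fixed_tau"), "fixed_value")
})

test_that("degenerate and undersized inputs raise estimation errors", {
  flat <- data.frame(time = 1:5, height = rep(3, 5))
  expect_error(fit_rise(flat), class = "csf_estimation_error")
  two <- data.frame(time = 1:2, height = 1:2)
  expect_error(fit_rise(two), class = "csf_estimation_error")
})

test_that("fit methods are mutually consistent", {
  d <- closed_form_dataset(p = 13, tau = 72)
  f <- fit_rise(d, fluid = fluid_properties(density = 1))
  expect_equal(fitted(f) + residuals(f), d$height)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, newdata = d$time), fitted(f), tolerance = 1e-9)
  expect_output(print(summary(f)), "time constant")
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_identical(sims, simulate(f, nsim = 3, seed = 9))
})

test_that("all nine bench rise replicates fit with R-squared >= 0.99", {
  fits <- lapply(load_fixture("table2"), fit_rise)
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  expect_true(all(r2 >= 0.99))
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
})

test_that("rms_error measures residuals against a supplied curve", {
  d <- closed_form_dataset(p = 13, tau = 72)
  expect_equal(rms_error(d, 13, 72), 0, tolerance = 1e-12)
  shifted <- rise_dataset(d$time, d$height + 0.5)
  expect_equal(rms_error(shifted, 13, 72), 0.5, tolerance = 1e-12)
  expect_error(rms_error(list(), 13, 72), "data")
  # the fit's own curve is locally optimal on a parameter grid
  f <- fit_rise(load_fixture("table2")[[1]])
  best <- rms_error(f$data, coef(f)[["p_inf"]], coef(f)[["tau"]])
  for (dp in c(-0.4, 0, 0.4)) {
    for (dtau in c(-8, 0, 8)) {
      expect_gte(rms_error(f$data, coef(f)[["p_inf"]] + dp,
                           coef(f)[["tau"]] + dtau) + 1e-12, best)
    }
  }
})

test_that("equilibration summary averages per needle and flags gaps", {
  eq <- equilibration_time_summary(load_fixture("table2"), 13)
  expect_equal(nrow(eq), 3)
  expect_equal(eq$n_replicates, rep(3L, 3))
  pajunk <- eq$mean_time[eq$needle == "22G Pajunk Sprotte"]
  expect_equal(round(pajunk), 256)
  single <- rise_dataset(c(10, 20), c(6, 13), needle = "solo")
  expect_equal(equilibration_time_summary(list(single), 13)$mean_time, 20)
  short <- rise_dataset(c(5, 9), c(3, 6), needle = "n", replicate = "M9")
  expect_error(equilibration_time_summary(list(short), 13), "M9")
})

test_that("times to percentages apply the inverse rise curve", {
  out <- times_to_percentages(60, c(33.3, 50, 66.7, 83.3, 91.7, 95.8))
  expect_equal(unname(out[2]), 41.6, tolerance = 1e-3)
  expect_true(all(diff(out) > 0))
  expect_equal(unname(times_to_percentages(25, 95.8)), 79.3,
               tolerance = 1e-3)
  f <- fit_rise(closed_form_dataset(13, 60))
  expect_equal(unname(times_to_percentages(f, 50)), 0.693 * 60,
               tolerance = 1e-3)
  expect_error(times_to_percentages(60, 100), "percentages")
})

test_that("tau-vs-R regression matches the normal equations", {
  ols <- function(x, y) {   # brute-force normal-equation oracle
    n <- length(x)
    b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
    a <- mean(y) - b * mean(x)
    c(a, b)
  }
  set.seed(5)
  for (i in 1:10) {
    d <- data.frame(R = runif(6, 500, 2500), tau = runif(6, 20, 160))
    f <- tau_r_regression(d)
    ref <- ols(d$R, d$tau)
    expect_equal(f$intercept, ref[1], tolerance = 1e-10)
    expect_equal(f$slope, ref[2], tolerance = 1e-10)
  }
  # exact points on a line are recovered exactly
  line <- data.frame(R = c(500, 1000, 2000), tau = 0.1 * c(500, 1000, 2000) - 5)
  fl <- suppressWarnings(tau_r_regression(line))  # lm warns on a perfect fit
  expect_equal(fl$slope, 0.1, tolerance = 1e-12)
  expect_equal(fl$intercept, -5, tolerance = 1e-12)
  expect_equal(fl$r_squared, 1, tolerance = 1e-12)
  expect_error(tau_r_regression(data.frame(R = c(1, 1), tau = c(2, 3))),
               "distinct")
})
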