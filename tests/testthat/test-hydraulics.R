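test_that("Poiseuille resistance follows the closed form and its scalings", {
  # hand-evaluated: 128 * 1e-5 * 8.8 / (pi * 0.041^4) = 1268.8
  expect_equal(poiseuille_resistance(d = 0.041, L = 8.8, mu = 1e-5),
               1268.8, tolerance = 1e-3)
  R0 <- poiseuille_resistance(0.03, 9, 1.02e-5)
  expect_equal(poiseuille_resistance(0.06, 9, 1.02e-5), R0 / 16)
  expect_equal(poiseuille_resistance(0.03, 18, 1.02e-5), R0 * 2)
  # exact d^-4 and L^1 scaling over random draws
  set.seed(11)
  for (i in 1:20) {
    d <- runif(1, 0.01, 0.1); L <- runif(1, 5, 12); k <- runif(1, 1.1, 4)
    expect_equal(poiseuille_resistance(k * d, L, 1e-5),
                 poiseuille_resistance(d, L, 1e-5) / k^4)
    expect_equal(poiseuille_resistance(d, k * L, 1e-5),
                 poiseuille_resistance(d, L, 1e-5) * k)
  }
  expect_error(poiseuille_resistance(0, 8.8, 1e-5), "d")
  expect_error(poiseuille_resistance(0.04, -1, 1e-5), "L")
  expect_error(poiseuille_resistance(0.04, 8.8, 0), "mu")
})

test_that("drop-weight flow rates reproduce the gravimetric formula", {
  fl <- fluid_properties(density = 1.0006)
  m1 <- drop_measurement(10, 0.57360, 25.5, 13)
  expect_equal(round(flow_rate_from_drops(m1, fl), 4), 0.0225)
  m2 <- drop_measurement(10, 0.54960, 51.8, 13)
  expect_equal(round(flow_rate_from_drops(m2, fl), 4), 0.0106)
  m0 <- drop_measurement(1, 0, 10, 13)
  expect_equal(flow_rate_from_drops(m0, fl), 0)
  expect_error(drop_measurement(10, 0.5, 0, 13), "duration")
  expect_error(drop_measurement(2.5, 0.5, 10, 13), "n_drops")
})

test_that("resistance from flow is Delta-P over Q and linear in Delta-P", {
  expect_equal(resistance_from_flow(15.02, 0.0225), 15.02 / 0.0225)
  expect_equal(resistance_from_flow(0, 0.02), 0)
  expect_equal(resistance_from_flow(26, 0.013),
               2 * resistance_from_flow(13, 0.013))
  expect_error(resistance_from_flow(13, 0), "q")
  expect_error(resistance_from_flow(13, -0.01), "q")
})

test_that("time constant tau = R*A/rho reproduces the bench values", {
  A <- manometer_spec(0.37)$area
  expect_equal(A, pi * 0.37^2 / 4)
  expect_equal(round(time_constant(667.9, A)), 72)
  expect_equal(round(time_constant(1411.3, A)), 152)
  expect_equal(round(time_constant(1028.7, A)), 111)
  # linear in R and A
  expect_equal(time_constant(2 * 667.9, A), 2 * time_constant(667.9, A))
  expect_equal(time_constant(667.9, 3 * A), 3 * time_constant(667.9, A))
  expect_error(time_constant(667.9, 0), "A")
})

test_that("rise curve hits the canonical fraction table and is monotone", {
  tau <- 72
  expect_equal(rise_height(0, 13, tau), 0)
  expect_equal(rise_height(2 * tau, 13, tau) / 13, 0.8647, tolerance = 1e-4)
  expect_equal(rise_height(0.693 * tau, 13, tau) / 13, 0.5, tolerance = 1e-3)
  fr <- rise_height(c(0.693, 1, 2, 3, 5) * tau, 100, tau)
  expect_equal(round(fr), c(50, 63, 86, 95, 99))
  expect_error(rise_height(-1, 13, tau), "t")
  # strictly increasing, bounded by p/rho, over random parameter draws
  set.seed(7)
  for (i in 1:25) {
    tau_i <- runif(1, 5, 300); p <- runif(1, 5, 40); rho <- runif(1, 1, 1.01)
    tt <- sort(runif(50, 0, 10 * tau_i))
    h <- rise_height(tt, p, tau_i, rho)
    expect_true(all(diff(h) > 0))
    expect_true(all(h < p / rho))
  }
})

test_that("time_to_fraction inverts the rise curve", {
  expect_equal(time_to_fraction(0.5, 1), 0.693, tolerance = 1e-3)
  expect_equal(time_to_fraction(0.99, 1), 4.605, tolerance = 1e-4)
  ratio <- time_to_fraction(0.99, 50) / time_to_fraction(0.5, 50)
  expect_equal(ratio, 6.64, tolerance = 1e-3)
  expect_equal(round(ratio), 7)
  expect_true(time_to_fraction(1e-9, 40) < 1e-6)
  expect_error(time_to_fraction(1, 72), "r")
  expect_error(time_to_fraction(0, 72), "r")
  # mutual inverse to 1e-12 relative
  set.seed(3)
  for (i in 1:25) {
    tau <- runif(1, 5, 300); p <- runif(1, 5, 40); r <- runif(1, 0.01, 0.99)
    t <- time_to_fraction(r, tau)
    expect_equal(rise_height(t, p, tau), r * p, tolerance = 1e-12)
  }
})

test_that("equilibrium extrapolation recovers the true pressure", {
  expect_equal(extrapolate_equilibrium(13 * (1 - exp(-1)), t = 72, tau = 72),
               13)
  # forward-simulate a tau = 111 curve at P = 24, invert on a grid
  tau <- 111; p <- 24
  tt <- seq(1, 10 * tau, length.out = 97)
  h <- rise_height(tt, p, tau)
  expect_equal(extrapolate_equilibrium(h, tt, tau), rep(p, 97),
               tolerance = 1e-9)
  # a reading at 5 tau is itself within 1% of equilibrium
  h5 <- rise_height(5 * tau, p, tau)
  expect_lt(abs(extrapolate_equilibrium(h5, 5 * tau, tau) - h5) / h5, 0.01)
  expect_error(extrapolate_equilibrium(6.5, 0, 72), "t")
})

test_that("low-pass cut-off and gain behave as a first-order filter", {
  expect_equal(signif(cutoff_frequency(50), 2), 0.0032)
  expect_equal(cutoff_frequency(25), 1 / (2 * pi * 25))
  expect_equal(cutoff_frequency(100), cutoff_frequency(50) / 2)
  expect_error(cutoff_frequency(0), "tau")
  expect_equal(gain(0, 50), 1)
  for (tau in c(5, 50, 200)) {
    expect_equal(gain(cutoff_frequency(tau), tau), 1 / sqrt(2))
  }
  expect_equal(gain(0.3, 50), 0.0106, tolerance = 1e-2)
  expect_error(gain(-0.1, 50), "f")
})

test_that("reservoir pressure drop obeys the ten-diameter rule", {
  man <- manometer_spec(0.37)
  ten <- reservoir_spec(10 * man$bore_diameter)
  expect_equal(reservoir_pressure_drop_fraction(ten, man, h_eq = 13), 0.01)
  expect_lte(reservoir_pressure_drop_fraction(ten, man, 13, p0 = 13), 0.01)
  expect_equal(
    reservoir_pressure_drop_fraction(reservoir_spec(5), man, 13, 13),
    (0.37 / 5)^2, tolerance = 1e-10)
  expect_lt(reservoir_pressure_drop_fraction(reservoir_spec(1e6), man, 13),
            1e-10)
  expect_error(reservoir_spec(0), "diameter")
})

test_that("component constructors enforce their invariants", {
  expect_error(fluid_properties(density = 0), "density")
  expect_error(needle_spec("x", length = 9), "inner_diameter or resistance")
  expect_error(needle_spec("x", length = 9, inner_diameter = 0.08,
                           outer_diameter = 0.07), "inner_diameter")
  asm <- bench_assembly(R = 667.9, bore = 0.37, rho = 1.0006)
  # stored tau always reproducible from components
  expect_equal(asm$tau, time_constant(asm$resistance, asm$manometer$area,
                                      asm$fluid$density))
  # geometry fallback when no measured resistance
  nd <- needle_spec("geom", length = 8.8, inner_diameter = 0.041)
  fl <- fluid_properties(viscosity = 1e-5)
  expect_equal(needle_resistance(nd, fl),
               poiseuille_resistance(0.041, 8.8, 1e-5))
  expect_equal(viscosity_cmh2o_s(1.002), 1.0218e-5, tolerance = 1e-4)
})
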