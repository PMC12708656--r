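test_that("closed-form growth rate: limits, orientations, threshold", {
  # optimal bend mode at infinite activity grows at 1/2 per tau_a
  p_inf <- model_params(A = 1e12)
  expect_equal(growth_rate(0, 2 * pi, p_inf), 0.5, tolerance = 1e-8)
  # the active term vanishes at 45 degrees: purely elastic decay
  p <- model_params(A = 700, R = 1.3)
  k <- 2 * pi * 3
  expect_equal(growth_rate(k, k, p), -(1.3 + 4) * (2 * k^2) / (4 * 700))
  expect_lt(growth_rate(k, k, p), 0)
  # marginal mode at the threshold
  pm <- model_params(A = 10 * pi^2)
  expect_equal(growth_rate(0, 2 * pi, pm), 0, tolerance = 1e-14)
  expect_error(growth_rate(0, 0, p), "zero wavevector")
})

test_that("critical activity closed form and monotonicity in R", {
  expect_equal(critical_activity(model_params(A = 1, R = 1)), 10 * pi^2)
  expect_equal(critical_activity(model_params(A = 1, R = 1)), 98.696,
               tolerance = 1e-4)
  # R -> 0 limit (no rotational viscosity)
  expect_equal(critical_activity(model_params(A = 1, R = 1e-12)),
               2 * (2 * pi)^2, tolerance = 1e-6)
  Rs <- c(0.5, 1, 2, 4)
  Ac <- vapply(Rs, function(R) critical_activity(model_params(A = 1, R = R)),
               numeric(1))
  expect_true(all(diff(Ac) > 0))
})

test_that("closed form agrees with the assembled single-mode system to 1e-10", {
  set.seed(17)
  for (i in 1:50) {
    kx <- 2 * pi * sample(-8:8, 1)
    ky <- 2 * pi * sample(-8:8, 1)
    if (kx == 0 && ky == 0) ky <- 2 * pi
    A <- runif(1, 20, 5000)
    R <- runif(1, 0.2, 5)
    S <- sample(c(-1, 1), 1)
    p <- model_params(A, R, S)
    expect_equal(growth_rate(kx, ky, p),
                 oracle_linear_eigenvalue(kx, ky, A, R, S),
                 tolerance = 1e-10)
  }
})

test_that("dispersion curve tabulates bend modes and crosses zero", {
  p <- model_params(A = 500)
  dc <- dispersion_curve(p, k_index_max = 8)
  expect_equal(dc$s_tau_a, growth_rate(rep(0, 8), dc$k, p))
  expect_equal(dc$s_tau_r, dc$s_tau_a * 500)
  expect_true(any(dc$s_tau_a > 0) && any(dc$s_tau_a < 0))
})

test_that("simulated modal growth matches the dispersion to 2%", {
  g <- make_grid(64)
  p <- model_params(A = 500)
  ic <- initial_condition(g, "single_mode", amplitude = 1e-6, mode = c(0, 1))
  dt <- integrator_config()$dt
  t_real <- round(0.1 / 500 / dt) * dt * 500   # whole steps, in tau_a
  tr <- run_simulation(ic, p, g, t_final = 0.1 / 500,
                       sample_every = 0.1 / 500)
  a0 <- mode_amplitude(ic$theta, 0, 1)
  a1 <- mode_amplitude(tr$state$theta, 0, 1)
  s_meas <- log(a1 / a0) / t_real
  expect_equal(s_meas, growth_rate(0, 2 * pi, p), tolerance = 0.02)
})
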