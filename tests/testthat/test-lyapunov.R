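g32 <- make_grid(32)

test_that("config validation", {
  expect_error(lyapunov_config(window = 2.5e-3, renorm_interval = 1e-3),
               "integer multiple")
  expect_error(lyapunov_config(norm0 = 0), "norm0")
  expect_error(lyapunov_config(m = 0), "positive integer")
})

test_that("MLE equals the time average of stretching numbers (identity)", {
  set.seed(31)
  inc <- rnorm(40, mean = 0.02, sd = 0.01)
  run <- structure(list(increments = matrix(inc, ncol = 1),
                        interval = 1e-3, window = 5e-3, m = 1),
                   class = "an_lyapunov_run")
  lam <- mle(run)
  ss <- stretching_series(run)
  expect_equal(lam, mean(ss$alpha))
  expect_equal(nrow(ss), 8)
  # synthetic constant exponential growth: every alpha equals the rate
  run2 <- structure(list(increments = matrix(rep(3e-3, 20), ncol = 1),
                         interval = 1e-3, window = 5e-3, m = 1),
                    class = "an_lyapunov_run")
  expect_equal(stretching_series(run2)$alpha, rep(3, 4))
  expect_equal(mle(run2), 3)
  # zero increments -> zero MLE
  expect_equal(mle(rep(0, 10), total_time = 1), 0)
  # partial trailing window is dropped with a warning
  run3 <- structure(list(increments = matrix(rep(1e-3, 23), ncol = 1),
                         interval = 1e-3, window = 5e-3, m = 1),
                    class = "an_lyapunov_run")
  expect_warning(ss3 <- stretching_series(run3), "partial trailing")
  expect_equal(nrow(ss3), 4)
})

test_that("deviation pipeline recovers a known single-mode eigenvalue within 1%", {
  # uniform aligned reference is an exact fixed point; a deviation seeded
  # on the optimal bend mode must grow at exactly the linear rate
  p <- model_params(A = 500)
  lam_pred <- 500 * growth_rate(0, 2 * pi, p)  # per tau_r
  lc <- lyapunov_config(m = 1)
  run <- evolve_with_deviation(initial_condition(g32, "aligned"), p, g32,
                               lyap = lc, t_total = 0.02,
                               init_deviations = list(mode_field(g32, 0, 1, 1)),
                               check_resolution = FALSE)
  expect_equal(mle(run), lam_pred, tolerance = 0.01)
  # rescaling amplitude does not affect the estimate (within 1%)
  run10 <- evolve_with_deviation(initial_condition(g32, "aligned"), p, g32,
                                 lyap = lyapunov_config(norm0 = 1e-5),
                                 t_total = 0.02,
                                 init_deviations = list(mode_field(g32, 0, 1, 1)),
                                 check_resolution = FALSE)
  expect_equal(mle(run10), mle(run), tolerance = 0.01)
})

test_that("all deviations decay below the instability threshold", {
  p <- model_params(A = 50)
  run <- evolve_with_deviation(initial_condition(g32, "aligned"), p, g32,
                               lyap = lyapunov_config(m = 2),
                               t_total = 5e-3, seed = 4)
  expect_true(all(run$increments <= 0))
})

test_that("renormalized deviations are orthonormal and the reference is unaffected", {
  ic <- initial_condition(g32, "random_smooth", amplitude = 0.05, seed = 6)
  p <- model_params(A = 300)
  run1 <- evolve_with_deviation(ic, p, g32, lyap = lyapunov_config(m = 1),
                                t_total = 4e-3, seed = 8,
                                check_resolution = FALSE)
  run3 <- evolve_with_deviation(ic, p, g32, lyap = lyapunov_config(m = 3),
                                t_total = 4e-3, seed = 8,
                                check_resolution = FALSE)
  # reference trajectory is bitwise independent of the number of companions
  expect_identical(run1$state$theta, run3$state$theta)
  # Gram-Schmidt postcondition: mutual orthogonality at norm0
  Wn <- run3$deviations / run3$norm0
  gram <- crossprod(Wn)
  expect_equal(gram, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  # spectrum is ordered and its leading exponent is the MLE
  sp <- lyapunov_spectrum(run3)
  expect_true(all(diff(sp$lambda) <= 0))
  expect_equal(sp$lambda[1], max(colSums(run3$increments)) /
                 (nrow(run3$increments) * run3$interval))
  run_m1 <- lyapunov_spectrum(run1)
  expect_equal(run_m1$lambda, mle(run1))
})

test_that("chaotic fraction separates laminar and chaotic peaks", {
  set.seed(12)
  expect_equal(chaotic_fraction(rnorm(400, 0, 0.5))$f_c, 0)
  expect_equal(chaotic_fraction(rnorm(400, 30, 1))$f_c, 1)
  mix <- c(rnorm(500, 0, 0.5), rnorm(500, 30, 1))
  cf <- chaotic_fraction(mix)
  expect_equal(cf$f_c, 0.5, tolerance = 3 * sqrt(0.25 / 1000))
  expect_true(cf$threshold > 2 && cf$threshold < 28)
  # unbalanced mixture
  mix2 <- c(rnorm(300, 0, 0.5), rnorm(700, 25, 2))
  expect_equal(chaotic_fraction(mix2)$f_c, 0.7, tolerance = 0.05)
  expect_error(chaotic_fraction(numeric(0)), "empty")
})
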