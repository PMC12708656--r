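g32 <- make_grid(32)
g64 <- make_grid(64)

test_that("uniform alignment is an exact fixed point of the ADI step", {
  p <- model_params(A = 3000)
  th <- matrix(1.1, 64, 64)
  out <- th
  for (i in 1:25) out <- adi_step(out, p, g64)
  expect_equal(out, th, tolerance = 1e-13)
})

test_that("pure-diffusion step matches the Peaceman-Rachford stability function", {
  p <- model_params(A = 500)
  cfg <- integrator_config(dt = 1.8e-5)
  eps <- 1e-6
  th <- mode_field(g64, 1, 0, eps)
  out <- adi_step(th, p, g64, cfg, flow_on = FALSE)
  z <- (cfg$dt / 2) * fd_lap_eig(1, 64)
  gfac <- (1 + z) / (1 - z)
  expect_equal(out, gfac * th, tolerance = 1e-10)
  # and the stability function is the exponential up to O(dt^2)
  expect_equal(gfac, exp(-4 * pi^2 * cfg$dt), tolerance = 1e-5)
})

test_that("deterministic evolution is bitwise reproducible", {
  set.seed(9)
  th <- matrix(rnorm(32^2, sd = 0.1), 32, 32)
  p <- model_params(A = 400)
  a <- run_simulation(th, p, g32, t_final = 5e-3, check_resolution = FALSE)
  b <- run_simulation(th, p, g32, t_final = 5e-3, check_resolution = FALSE)
  expect_identical(a$state$theta, b$state$theta)
  expect_identical(a$diagnostics, b$diagnostics)
})

test_that("halving dt converges at first order or better", {
  ic <- initial_condition(g32, "random_smooth", amplitude = 0.05, seed = 21)
  p <- model_params(A = 300)
  Tfin <- 1.6e-3
  sol <- lapply(c(4e-5, 2e-5, 1e-5), function(dt) {
    run_simulation(ic, p, g32, integrator_config(dt = dt),
                   t_final = Tfin, check_resolution = FALSE)$state$theta
  })
  e1 <- max(abs(sol[[1]] - sol[[2]]))
  e2 <- max(abs(sol[[2]] - sol[[3]]))
  expect_gte(e1 / e2, 1.8)
})

test_that("noise injection has the stated per-node amplitude and is unbiased", {
  g256 <- make_grid(256)
  spec <- noise_spec(D = 5e-4, duration = 1e-2)
  th0 <- matrix(0, 256, 256)
  set.seed(1)
  xi <- inject_noise(th0, spec, dt = 1.8e-5, g256)
  sd_pred <- sqrt(2 * 5e-4 * 1.8e-5) * 256
  expect_equal(sd_pred, 3.434e-2, tolerance = 1e-3)
  expect_equal(sd(as.numeric(xi)), sd_pred, tolerance = 0.02)
  se <- sd_pred / 256
  expect_lt(abs(mean(xi)), 4 * se)
  # D = 0 is the identity
  expect_identical(inject_noise(th0, noise_spec(D = 0), 1.8e-5, g256), th0)
})

test_that("same noise seed gives bitwise-identical trajectories", {
  p <- model_params(A = 200)
  ns <- noise_spec(D = 5e-4, duration = 5 * 1.8e-5, seed = 77)
  a <- run_simulation(initial_condition(g32, "aligned"), p, g32,
                      noise = ns, t_final = 2e-3)
  b <- run_simulation(initial_condition(g32, "aligned"), p, g32,
                      noise = ns, t_final = 2e-3)
  expect_identical(a$state$theta, b$state$theta)
})

test_that("sub-threshold MSV decays monotonically after the noise burst", {
  p <- model_params(A = 50)  # below the instability threshold
  ns <- noise_spec(D = 5e-4, duration = 1e-3, seed = 5)
  tr <- run_simulation(initial_condition(g32, "aligned"), p, g32,
                      noise = ns, t_final = 0.05, sample_every = 5e-3)
  d <- tr$diagnostics
  post <- d$msv[d$time > 2e-3]
  expect_true(all(diff(post) < 0))
  expect_lt(post[length(post)] / post[1], 0.5)
})

test_that("extensile and contractile runs are equivalent under a pi/2 rotation", {
  set.seed(13)
  th <- matrix(rnorm(64^2, sd = 0.05), 64, 64)
  pc <- model_params(A = 300, S = -1)
  pe <- model_params(A = 300, S = +1)
  a <- th + pi / 2
  b <- th
  for (i in 1:10) {
    a <- adi_step(a, pc, g64)
    b <- adi_step(b, pe, g64)
  }
  # exact in exact arithmetic; rounding differences are amplified slightly
  # over the ten steps
  expect_equal(a - pi / 2, b, tolerance = 1e-10)
  # the slaved flows also coincide
  fa <- solve_stream_function(a, pc, g64)
  fb <- solve_stream_function(b, pe, g64)
  expect_equal(fa$psi, fb$psi, tolerance = 1e-12)
})
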