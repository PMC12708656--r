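g64 <- make_grid(64)

test_that("MSV closed forms and exact decomposition", {
  z <- matrix(0, 64, 64)
  expect_equal(unlist(msv(flow_obj(z, z))[c("msv", "msv_x", "msv_y")]),
               c(msv = 0, msv_x = 0, msv_y = 0))
  vx <- 2 * pi * outer(rep(1, 64), cos(2 * pi * g64$y))
  m <- msv(flow_obj(vx, z))
  expect_equal(m$msv_x, 2 * pi^2)   # mean of squared cosine is 1/2
  expect_equal(m$msv_y, 0)
  set.seed(2)
  fl <- flow_obj(matrix(rnorm(64^2), 64, 64), matrix(rnorm(64^2), 64, 64))
  m <- msv(fl)
  expect_identical(m$msv, m$msv_x + m$msv_y)
})

test_that("MSV in tau_r units is A^2 times the tau_a value", {
  set.seed(14)
  th <- matrix(rnorm(64^2, sd = 0.2), 64, 64)
  A <- 700
  fa <- solve_stream_function(th, model_params(A, time_unit = "tau_a"), g64)
  fr <- solve_stream_function(th, model_params(A, time_unit = "tau_r"), g64)
  expect_equal(msv(fr)$msv, A^2 * msv(fa)$msv, tolerance = 1e-12)
})

test_that("enstrophy kymograph matches the R-side vorticity oracle", {
  p <- model_params(A = 200, time_unit = "tau_a")
  g32 <- make_grid(32)
  ic <- initial_condition(g32, "random_smooth", amplitude = 0.1, seed = 3)
  tr <- run_simulation(ic, p, g32, t_final = 4e-3, sample_every = 1e-3,
                       snapshot_every = 1e-3)
  ky <- enstrophy_kymograph(tr)
  expect_true(all(ky$eps >= 0))
  expect_equal(ncol(ky$eps), length(tr$snapshots))
  # cross-check one column against the independent spectral pipeline
  th <- tr$snapshots[[2]]
  psi_or <- oracle_stream_psi(th, 200, 1, -1, g32)
  om_or <- vorticity_from_stream(psi_or, g32)
  expect_equal(ky$eps[, 2], rowMeans(om_or^2), tolerance = 1e-10)
  # quiescent trajectory: identically zero
  trq <- run_simulation(initial_condition(g32, "aligned"), p, g32,
                        t_final = 2e-3, snapshot_every = 1e-3)
  expect_equal(max(enstrophy_kymograph(trq)$eps), 0)
})

test_that("oscillation fit recovers synthetic parameters", {
  t <- seq(0, 2, by = 1e-3)
  y <- exp(-2 * t) * sin(2 * pi * 7 * t)
  f <- fit_oscillation(t, y)
  expect_true(f$oscillatory)
  expect_equal(f$decay_rate, -2, tolerance = 1e-3)
  expect_equal(f$frequency, 7, tolerance = 1e-3)
  # 5% additive noise: recovery within 5%
  set.seed(19)
  yn <- y + rnorm(length(y), sd = 0.05 * max(abs(y)))
  fn <- fit_oscillation(t, yn)
  expect_equal(fn$decay_rate, -2, tolerance = 0.05)
  expect_equal(fn$frequency, 7, tolerance = 0.05)
  # pure exponential decay is flagged non-oscillatory
  fe <- fit_oscillation(t, 3 * exp(-1.5 * t))
  expect_false(fe$oscillatory)
  expect_equal(fe$frequency, 0)
})

test_that("flow-state classifier labels synthetic windows", {
  t <- seq(0, 1, by = 1e-2)
  quiet <- data.frame(time = t, msv = rep(0, length(t)))
  expect_equal(classify_flow_state(quiet), "quiescent")
  steady <- data.frame(time = t, msv = 5 + 1e-9 * sin(2 * pi * 8 * t))
  expect_equal(classify_flow_state(steady), "laminar_steady")
  osc <- data.frame(time = t, msv = 5 + 0.5 * sin(2 * pi * 8 * t))
  expect_equal(classify_flow_state(osc), "laminar_oscillatory")
  expect_equal(classify_flow_state(osc, alpha = rep(30, 50)), "chaotic")
  expect_error(classify_flow_state(data.frame(time = t / 10, msv = t)),
               "too short")
})

test_that("vortex counting distinguishes shear from vortex arrays", {
  # shear: psi depends on y only -> no isolated extrema
  shear <- flow_obj(matrix(0, 64, 64), matrix(0, 64, 64),
                    psi = outer(rep(1, 64), sin(2 * pi * g64$y)))
  expect_equal(count_vortices(shear), 0)
  # 2x2 vortex lattice: four extrema
  lat <- flow_obj(matrix(0, 64, 64), matrix(0, 64, 64),
                  psi = outer(sin(2 * pi * g64$x), sin(2 * pi * g64$y)))
  expect_equal(count_vortices(lat), 4)
})
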