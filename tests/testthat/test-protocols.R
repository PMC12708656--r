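test_that("ramp schedules validate their invariants", {
  expect_error(ramp_schedule(from = 100, to = 200, dA = 0, relax_time = 1),
               "nonzero")
  expect_error(ramp_schedule(from = 200, to = 100, dA = 10, relax_time = 1),
               "wrong sign")
  expect_error(ramp_schedule(A_values = c(100, 100, 120), relax_time = 1),
               "monotone")
  expect_error(ramp_schedule(A_values = c(100, 120), relax_time = 0),
               "relax_time")
  s <- ramp_schedule(from = 100, to = 50, dA = -25, relax_time = 0.5)
  expect_equal(s$direction, "down")
  expect_equal(s$A_values, c(100, 75, 50))
})

test_that("down-ramp entirely below the threshold stays quiescent", {
  g <- make_grid(32)
  p <- model_params(A = 60)
  ic <- initial_condition(g, "aligned_noise", sd = 1e-4, seed = 3)
  sch <- ramp_schedule(from = 60, to = 30, dA = -15, relax_time = 0.3)
  br <- activity_ramp(ic, sch, p, g)
  expect_true(all(br$points$msv < 1e-10))
  # and the field itself has relaxed toward uniform alignment
  expect_lt(max(abs(br$state$theta - mean(br$state$theta))), 1e-5)
})

test_that("up-ramp departs from quiescence at the step bracketing the threshold", {
  g <- make_grid(64)
  p <- model_params(A = 90)
  sch <- ramp_schedule(from = 85, to = 115, dA = 5, relax_time = 0.5,
                       noise = noise_spec(D = 5e-6, duration = 1e-3))
  br <- activity_ramp(initial_condition(g, "aligned"), sch, p, g, seed = 31)
  pts <- br$points
  # detector: does the seeded perturbation grow or decay over the window?
  growing <- pts$A[!is.na(pts$growth) & pts$growth > 1]
  expect_gt(length(growing), 0)
  onset <- min(growing)
  Ac <- critical_activity(p)             # 10*pi^2 = 98.7
  expect_gt(onset, Ac - 5)
  expect_lte(onset, Ac + 7.5)
})

test_that("hysteresis loop inside a single laminar branch finds no jumps", {
  g <- make_grid(64)
  p <- model_params(A = 150)
  # start from a converged shear state
  est <- run_simulation(initial_condition(g, "aligned"), p, g,
                        noise = noise_spec(5e-6, 1e-3, seed = 7),
                        t_final = 1)
  hy <- hysteresis_loop(est$state, A_min = 150, A_max = 190, dA = 10,
                        relax = 0.4, params = p, grid = g)
  expect_true(is.na(hy$up_jump))
  expect_true(is.na(hy$down_jump))
  # branches coincide within 1% where they overlap
  up <- hy$up$points[order(hy$up$points$A), ]
  dn <- hy$down$points[order(hy$down$points$A), ]
  expect_equal(dn$msv, up$msv, tolerance = 0.01)
  # MSV grows along the branch
  expect_true(all(diff(up$msv) > 0))
})

test_that("sub-threshold ensemble is fully laminar with f_c = 0", {
  g <- make_grid(32)
  p <- model_params(A = 50)
  scan <- ensemble_transition_scan(50, p, g, n_realizations = 3, t_f = 0.5,
                                   noise = noise_spec(5e-4, 1e-3),
                                   master_seed = 17)
  expect_true(all(vapply(scan$realizations[["50"]],
                         function(r) is.null(r$error), logical(1))))
  expect_lt(scan$table$msv_mean, 1e-8)
  expect_lt(scan$table$mle_mean, 0)
  expect_equal(scan$table$f_c, 0)
})

test_that("ensemble means from disjoint seed sets agree within 3 sem", {
  g <- make_grid(32)
  p <- model_params(A = 200)  # above threshold: finite-MSV shear state
  s1 <- ensemble_transition_scan(200, p, g, n_realizations = 3, t_f = 0.4,
                                 noise = noise_spec(5e-4, 1e-3),
                                 master_seed = 100)
  s2 <- ensemble_transition_scan(200, p, g, n_realizations = 3, t_f = 0.4,
                                 noise = noise_spec(5e-4, 1e-3),
                                 master_seed = 900)
  m1 <- s1$table$msv_mean; m2 <- s2$table$msv_mean
  sem <- sqrt(s1$table$msv_sem^2 + s2$table$msv_sem^2)
  expect_lt(abs(m1 - m2), 3 * max(sem, 1e-12))
})
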