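# The Stokes solve is the slaved part of the dynamics: psi follows theta
# instantaneously. These tests pin it against closed forms and an
# independent R-side spectral oracle.

g64 <- make_grid(64)
pa <- model_params(A = 500, R = 1, S = -1, time_unit = "tau_a")

test_that("uniform director drives no flow", {
  for (const in c(0, 0.7, -2)) {
    fl <- solve_stream_function(matrix(const, 64, 64), pa, g64)
    expect_equal(max(abs(fl$psi)), 0)
    expect_equal(max(abs(fl$vx)), 0)
    expect_equal(max(abs(fl$vy)), 0)
  }
})

test_that("single bend mode reproduces the linearized closed form", {
  eps <- 1e-6
  th <- mode_field(g64, 0, 1, eps)
  fl <- solve_stream_function(th, pa, g64)
  # psi_hat = [-R/(2A) + S (kx^2-ky^2)/k^4] theta_hat with kx=0, ky=2*pi
  pred <- (1 / (4 * pi^2) - 1 / (2 * 500)) * th
  expect_lt(max(abs(fl$psi - pred)), 1e-12 * eps / 1e-6)
})

test_that("compiled solver matches the R spectral oracle on rough fields", {
  set.seed(42)
  for (S in c(-1, 1)) {
    th <- matrix(rnorm(64^2, sd = 0.3), 64, 64)
    p <- model_params(A = 800, R = 1.7, S = S, time_unit = "tau_a")
    fl <- solve_stream_function(th, p, g64)
    psi_or <- oracle_stream_psi(th, 800, 1.7, S, g64)
    expect_lt(max(abs(fl$psi - psi_or)), 1e-10 * max(abs(psi_or)))
  }
})

test_that("solve is equivariant under grid translations", {
  set.seed(7)
  th <- matrix(rnorm(64^2, sd = 0.2), 64, 64)
  sh <- function(m) m[c(2:64, 1), ]
  f1 <- solve_stream_function(sh(th), pa, g64)$psi
  f2 <- sh(solve_stream_function(th, pa, g64)$psi)
  expect_lt(max(abs(f1 - f2)), 1e-12)
})

test_that("velocity from stream: closed form and spectral incompressibility", {
  psi <- outer(rep(1, 64), sin(2 * pi * g64$y))
  v <- velocity_from_stream(psi, g64)
  expect_equal(v$vx, 2 * pi * outer(rep(1, 64), cos(2 * pi * g64$y)),
               tolerance = 1e-10)
  expect_equal(max(abs(v$vy)), 0, tolerance = 1e-12)
  expect_equal(velocity_from_stream(matrix(3, 64, 64), g64)$vx,
               matrix(0, 64, 64), tolerance = 1e-12)

  set.seed(3)
  th <- matrix(rnorm(64^2, sd = 0.3), 64, 64)
  v <- velocity_from_stream(solve_stream_function(th, pa, g64)$psi, g64)
  div_h <- sweep(stats::fft(v$vx), 1, 1i * g64$kx, `*`) +
    sweep(stats::fft(v$vy), 2, 1i * g64$ky, `*`)
  expect_lt(max(Mod(div_h)) / 64^2, 1e-10)
})

test_that("vorticity from stream matches -laplacian and is equivariant", {
  psi <- outer(rep(1, 64), sin(2 * pi * g64$y))
  om <- vorticity_from_stream(psi, g64)
  expect_equal(om, 4 * pi^2 * psi, tolerance = 1e-10)
  expect_equal(max(abs(vorticity_from_stream(matrix(1, 64, 64), g64))), 0,
               tolerance = 1e-12)
  set.seed(8)
  psi <- matrix(rnorm(64^2), 64, 64)
  sh <- function(m) m[, c(5:64, 1:4)]
  expect_equal(vorticity_from_stream(sh(psi), g64),
               sh(vorticity_from_stream(psi, g64)), tolerance = 1e-9)
})

test_that("shape and finiteness errors are raised", {
  expect_error(solve_stream_function(matrix(0, 32, 32), pa, g64), "shape")
  th <- matrix(0, 64, 64); th[1, 1] <- NaN
  expect_error(solve_stream_function(th, pa, g64), "finite")
  expect_error(velocity_from_stream(matrix(0, 16, 16), g64), "mismatch")
})
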