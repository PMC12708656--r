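# Shared fixtures and independent oracles, all built in code.

# A single Fourier mode theta = eps * sin(2*pi*(mx*x + my*y))
mode_field <- function(grid, mx, my, eps = 1e-6, phase = 0) {
  eps * sin(outer(grid$x, grid$y,
                  function(x, y) 2 * pi * (mx * x + my * y)) + phase)
}

# Independent spectral Stokes oracle using R's fft (separate code path
# from the compiled solver): psi_hat = mask * [ -R/(2A) theta_hat
#   + S (0.5 (kx^2-ky^2) S2_hat - kx ky C2_hat) / k^4 ]
oracle_stream_psi <- function(theta, A, R, S, grid) {
  n <- grid$n
  kx <- grid$kx; ky <- grid$ky
  KX <- matrix(kx, n, n); KY <- matrix(ky, n, n, byrow = TRUE)
  K2 <- KX^2 + KY^2
  K4 <- K2^2; K4[1, 1] <- 1
  th_h <- stats::fft(theta)
  s2_h <- stats::fft(sin(2 * theta))
  c2_h <- stats::fft(cos(2 * theta))
  psi_h <- -R / (2 * A) * th_h +
    S * (0.5 * (KX^2 - KY^2) * s2_h - KX * KY * c2_h) / K4
  psi_h[!grid$dealias] <- 0
  psi_h[1, 1] <- 0
  Re(stats::fft(psi_h, inverse = TRUE)) / n^2
}

# eigenvalue of the assembled single-mode linear system about theta = 0:
# first solve the Stokes balance for psi_hat given theta_hat, then feed it
# into the linearized director equation (tau_a units)
oracle_linear_eigenvalue <- function(kx, ky, A, R, S) {
  k2 <- kx^2 + ky^2
  psi_fac <- -R / (2 * A) + S * (kx^2 - ky^2) / k2^2
  (k2 / 2) * psi_fac - k2 / A
}

# amplitude of mode (mx, my) in a real field
mode_amplitude <- function(theta, mx, my) {
  n <- nrow(theta)
  2 * Mod(stats::fft(theta)[(mx %% n) + 1, (my %% n) + 1]) / n^2
}

# finite-difference Laplacian eigenvalue for mode number m on n points
fd_lap_eig <- function(m, n) {
  (2 * cos(2 * pi * m / n) - 2) * n^2
}

# manual an_flow constructor for observable tests
flow_obj <- function(vx, vy, psi = NULL, omega = NULL,
                     time_unit = "tau_a", time = 0) {
  structure(list(psi = psi, vx = vx, vy = vy, omega = omega,
                 time = time, time_unit = time_unit),
            class = "an_flow")
}
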