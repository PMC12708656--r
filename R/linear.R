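#' Linear growth rate of perturbations of the aligned state
#'
#' Closed-form dispersion relation of the spontaneous-flow instability.
#' Linearizing the Stokes balance and director dynamics about the uniformly
#' aligned state \eqn{\theta = 0} for a single Fourier mode
#' \eqn{e^{i(k_x x + k_y y)}} gives the real growth rate
#' \deqn{s(k_x, k_y) = S\,\frac{k_x^2 - k_y^2}{2 k^2}
#'   - \frac{(R + 4)\,k^2}{4 A}, \qquad k^2 = k_x^2 + k_y^2,}
#' in \eqn{1/\tau_a} (multiply by \eqn{A} for \eqn{1/\tau_r}). The active
#' term is maximal for pure bend of the optimal orientation (for a
#' contractile system aligned along x, wavevectors along y) and vanishes at
#' 45 degrees; the elastic term always stabilizes. The primary instability
#' is stationary: \eqn{s} is real, so no oscillations accompany it.
#'
#' @param kx,ky Wavevector components (multiples of \eqn{2\pi} on the unit
#'   square); vectors are recycled elementwise. The zero wavevector is
#'   rejected.
#' @param params [model_params()].
#' @return Growth rate(s) in \eqn{1/\tau_a}.
#' @examples
#' p <- model_params(A = 10 * pi^2)
#' growth_rate(0, 2 * pi, p)  # 0: the marginal mode at the threshold
#' @export
growth_rate <- function(kx, ky, params) {
  stopifnot(inherits(params, "an_params"))
  k2 <- kx^2 + ky^2
  if (any(k2 == 0)) stop("zero wavevector has no growth rate")
  params$S * (kx^2 - ky^2) / (2 * k2) - (params$R + 4) * k2 / (4 * params$A)
}

#' Critical activity of the spontaneous-flow instability
#'
#' The smallest activity at which any periodic mode becomes marginal.
#' Setting \eqn{s = 0} at the optimally oriented mode gives
#' \eqn{A_c = (R + 4)\,k_{\min}^2 / 2}; on the unit square the lowest
#' nonzero wavenumber is \eqn{k_{\min} = 2\pi}, so for \eqn{R = 1} the
#' first bifurcation sits at \eqn{A_c = 10\pi^2 \approx 98.7}.
#'
#' @param params [model_params()] (only \code{R} matters).
#' @param k_min Smallest admissible wavenumber magnitude (default
#'   \eqn{2\pi}).
#' @return The critical activity number.
#' @export
critical_activity <- function(params, k_min = 2 * pi) {
  stopifnot(inherits(params, "an_params"))
  (params$R + 4) * k_min^2 / 2
}

#' Dispersion curve along the most unstable orientation
#'
#' Tabulates \eqn{s(k)} for bend modes (wavevector perpendicular to the
#' aligned contractile director, i.e. \eqn{k_x = 0} for \eqn{S = -1}),
#' where the active destabilization is strongest.
#'
#' @param params [model_params()].
#' @param k_index_max Largest integer mode number to include (default 8).
#' @return data.frame with columns \code{k_index}, \code{k}, \code{s_tau_a},
#'   \code{s_tau_r}.
#' @export
dispersion_curve <- function(params, k_index_max = 8) {
  m <- seq_len(k_index_max)
  k <- 2 * pi * m
  s <- if (params$S < 0) growth_rate(0, k, params) else growth_rate(k, 0, params)
  data.frame(k_index = m, k = k, s_tau_a = s, s_tau_r = s * params$A)
}
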