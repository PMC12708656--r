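#' Instantaneous Stokes flow generated by the director field
#'
#' At zero Reynolds number the flow is slaved to the director: taking the
#' curl of the force balance gives the biharmonic problem
#' \deqn{-\nabla^4 \psi = \frac{R}{2A}\nabla^4\theta +
#'   S\left[\tfrac12(\partial_x^2-\partial_y^2)\sin 2\theta -
#'   \partial^2_{xy}\cos 2\theta\right],}
#' solved spectrally on the periodic grid with the 2/3 anti-aliasing rule
#' applied to the right-hand side. The undetermined zero mode of
#' \eqn{\psi} is set to zero (velocities only involve derivatives of
#' \eqn{\psi}, so this gauge choice has no dynamical effect).
#'
#' @param theta An \code{an_field} or a square matrix of director angles.
#' @param params [model_params()]. The fields are returned in the
#'   velocity/time unit selected by \code{params$time_unit}
#'   (\eqn{v[L/\tau_r] = A\, v[L/\tau_a]}).
#' @param grid [make_grid()] matching the field.
#' @return An object of class \code{an_flow}: list with matrices
#'   \code{psi} (stream function), \code{vx} (\eqn{=\partial_y\psi}),
#'   \code{vy} (\eqn{=-\partial_x\psi}), \code{omega}
#'   (vorticity \eqn{=-\nabla^2\psi}), plus \code{time_unit} and the
#'   field's \code{time}.
#' @examples
#' g <- make_grid(64)
#' p <- model_params(A = 500, time_unit = "tau_a")
#' fl <- solve_stream_function(initial_condition(g, "aligned"), p, g)
#' max(abs(fl$psi))  # 0: uniform alignment drives no flow
#' @export
solve_stream_function <- function(theta, params, grid) {
  stopifnot(inherits(params, "an_params"), inherits(grid, "an_grid"))
  th <- check_field(theta, grid)
  res <- cpp_stream(th, params$A, params$R, params$S)
  u <- unit_factor(params)
  structure(list(psi = res$psi * u, vx = res$vx * u, vy = res$vy * u,
                 omega = res$omega * u,
                 time = if (inherits(theta, "an_field")) theta$time else NA_real_,
                 time_unit = params$time_unit),
            class = "an_flow")
}

#' @export
print.an_flow <- function(x, ...) {
  cat(sprintf("<an_flow> %d x %d, max|v| = %.4g L/%s\n",
              nrow(x$psi), ncol(x$psi),
              max(abs(x$vx), abs(x$vy)), x$time_unit))
  invisible(x)
}

#' Velocity from a stream function
#'
#' Spectral differentiation of \eqn{\psi}: \eqn{v_x = \partial_y \psi},
#' \eqn{v_y = -\partial_x \psi}. The resulting velocity field is
#' divergence-free to spectral precision by construction.
#'
#' @param psi Square matrix (any units; derivatives carry the units through).
#' @param grid Matching [make_grid()].
#' @return List with matrices \code{vx}, \code{vy}.
#' @export
velocity_from_stream <- function(psi, grid) {
  psi <- as.matrix(psi)
  if (nrow(psi) != grid$n || ncol(psi) != grid$n) stop("shape mismatch")
  if (!all(is.finite(psi))) stop("psi must be finite")
  ph <- stats::fft(psi)
  dk_x <- sweep(ph, 1, 1i * grid$kx, `*`)
  dk_y <- sweep(ph, 2, 1i * grid$ky, `*`)
  n2 <- grid$n^2
  list(vx = Re(stats::fft(dk_y, inverse = TRUE)) / n2,
       vy = -Re(stats::fft(dk_x, inverse = TRUE)) / n2)
}

#' Vorticity from a stream function
#'
#' \eqn{\omega = \partial_x v_y - \partial_y v_x = -\nabla^2 \psi},
#' evaluated spectrally.
#'
#' @inheritParams velocity_from_stream
#' @return Matrix \code{omega}.
#' @export
vorticity_from_stream <- function(psi, grid) {
  psi <- as.matrix(psi)
  if (nrow(psi) != grid$n || ncol(psi) != grid$n) stop("shape mismatch")
  ph <- stats::fft(psi)
  k2 <- outer(grid$kx^2, grid$ky^2, `+`)
  Re(stats::fft(k2 * ph, inverse = TRUE)) / grid$n^2
}

#' Right-hand side of the director-angle dynamics
#'
#' Evaluates
#' \deqn{\partial_t\theta = -(\partial_y\psi)(\partial_x\theta)
#'   + (\partial_x\psi)(\partial_y\theta) - \tfrac12\nabla^2\psi
#'   + \tfrac1A \nabla^2\theta}
#' (stated in \eqn{\tau_a} time units; with \code{time_unit = "tau_r"} the
#' whole expression is multiplied by \eqn{A}, making the elastic diffusion
#' coefficient exactly 1). Mirroring the integrator's mixed discretization,
#' derivatives of \eqn{\psi} are spectral while derivatives of \eqn{\theta}
#' are second-order centered finite differences.
#'
#' @param theta Director field (matrix or \code{an_field}).
#' @param flow An \code{an_flow} consistent with \code{theta} (the caller's
#'   responsibility), e.g. from [solve_stream_function()].
#' @param params,grid Model parameters and grid.
#' @return Matrix of time derivatives of \eqn{\theta}, in
#'   1/\code{params$time_unit}.
#' @export
director_tendency <- function(theta, flow, params, grid) {
  stopifnot(inherits(flow, "an_flow"))
  th <- check_field(theta, grid)
  # bring psi derivatives to tau_a units, assemble there, convert at the end
  fu <- if (identical(flow$time_unit, "tau_r")) params$A else 1
  dpsi_dy <- flow$vx / fu
  dpsi_dx <- -flow$vy / fu
  lap_psi <- -flow$omega / fu
  dx <- grid$dx
  dth_dx <- (shift_mat(th, -1, 1) - shift_mat(th, 1, 1)) / (2 * dx)
  dth_dy <- (shift_mat(th, -1, 2) - shift_mat(th, 1, 2)) / (2 * dx)
  lap_th <- (shift_mat(th, -1, 1) + shift_mat(th, 1, 1) +
             shift_mat(th, -1, 2) + shift_mat(th, 1, 2) - 4 * th) / dx^2
  out <- -dpsi_dy * dth_dx + dpsi_dx * dth_dy - 0.5 * lap_psi +
    lap_th / params$A
  out * unit_factor(params)
}

# internal: circular shift of a matrix by one cell along axis (1 = rows/x,
# 2 = cols/y); by = +1 shifts contents toward higher indices
shift_mat <- function(m, by, axis) {
  n <- if (axis == 1) nrow(m) else ncol(m)
  idx <- ((seq_len(n) - 1 - by) %% n) + 1
  if (axis == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}
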