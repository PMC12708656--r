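#' Mean squared velocity
#'
#' The flow-intensity diagnostic \eqn{\langle v^2\rangle_r} and its
#' components, grid-averaged. The decomposition
#' \code{msv = msv_x + msv_y} holds exactly. Units are
#' \eqn{(L/\tau)^2} in the flow's time unit.
#'
#' @param flow An \code{an_flow} (see [solve_stream_function()]).
#' @return data.frame row: \code{time}, \code{msv}, \code{msv_x},
#'   \code{msv_y}.
#' @export
msv <- function(flow) {
  stopifnot(inherits(flow, "an_flow"))
  mx <- mean(flow$vx^2)
  my <- mean(flow$vy^2)
  data.frame(time = flow$time, msv = mx + my, msv_x = mx, msv_y = my)
}

#' Enstrophy kymograph
#'
#' Space-time diagram of the y-averaged enstrophy
#' \eqn{\epsilon(x, t) = \langle |\omega(x, y, t)|^2 \rangle_y}, the
#' diagnostic that reveals whether the transition to chaos is spatially
#' global (all x turning chaotic at once, as for long-ranged Stokes
#' interactions) or proceeds by localized turbulent patches.
#'
#' @param traj An \code{an_trajectory} with stored snapshots
#'   (\code{snapshot_every} finite in [run_simulation()]).
#' @return Object of class \code{an_kymograph}: \code{$x} (coordinates),
#'   \code{$time}, and \code{$eps} (matrix, rows = x, cols = time), in the
#'   trajectory's value unit.
#' @export
enstrophy_kymograph <- function(traj) {
  stopifnot(inherits(traj, "an_trajectory"))
  if (length(traj$snapshots) == 0) stop("trajectory has no snapshots")
  p <- traj$params
  u <- unit_factor(p)
  eps <- vapply(traj$snapshots, function(th) {
    fl <- cpp_stream(th, p$A, p$R, p$S)
    rowMeans((fl$omega * u)^2)
  }, numeric(traj$grid$n))
  structure(list(x = traj$grid$x, time = traj$snapshot_times,
                 eps = matrix(eps, traj$grid$n),
                 time_unit_values = p$time_unit),
            class = "an_kymograph")
}

#' @export
print.an_kymograph <- function(x, ...) {
  cat(sprintf("<an_kymograph> %d x-bins x %d times, max eps = %.4g\n",
              length(x$x), length(x$time), max(x$eps)))
  invisible(x)
}

#' Fit a decaying (or growing) oscillation
#'
#' Near a pair of complex-conjugate eigenvalues, the relaxation of a
#' perturbed steady state follows
#' \eqn{\langle\delta v^2\rangle \propto e^{\lambda t}\sin(2\pi\omega t +
#' \phi)}. This fits that four-parameter model by nonlinear least squares
#' (Levenberg-Marquardt), with deterministic initial guesses: the
#' frequency from the dominant periodogram peak and the decay rate from
#' the slope of the log envelope.
#'
#' @param time Sample times (uniformly spaced recommended).
#' @param dv2 The signed deviation signal \eqn{\langle\delta v^2\rangle}.
#' @param peak_factor A spectral peak is deemed significant when it
#'   exceeds this multiple of the median periodogram level (default 5);
#'   otherwise the series is flagged non-oscillatory.
#' @return Object of class \code{an_oscillation_fit}: \code{$decay_rate}
#'   (\eqn{\lambda}), \code{$frequency} (\eqn{\omega}), \code{$amplitude},
#'   \code{$phase}, \code{$residual} (RMS), \code{$oscillatory} (logical).
#'   For non-oscillatory input the exponential-only fit is returned with
#'   \code{frequency = 0}.
#' @examples
#' t <- seq(0, 2, by = 1e-3)
#' y <- exp(-2 * t) * sin(2 * pi * 7 * t)
#' f <- fit_oscillation(t, y)
#' c(f$decay_rate, f$frequency)  # close to (-2, 7)
#' @export
fit_oscillation <- function(time, dv2, peak_factor = 5) {
  stopifnot(length(time) == length(dv2), length(time) >= 8)
  o <- order(time)
  time <- time[o]; dv2 <- dv2[o]
  dt <- stats::median(diff(time))
  y <- dv2 - 0  # the model passes through zero; no de-meaning
  # periodogram for the initial frequency guess
  sp <- Mod(stats::fft(y - mean(y)))^2
  half <- 2:(floor(length(y) / 2))
  freqs <- (half - 1) / (length(y) * dt)
  pk <- which.max(sp[half])
  # a monotone decay also has a low-frequency spectral peak, so demand
  # genuine sign alternation as well
  n_cross <- sum(abs(diff(sign(y[y != 0]))) > 0)
  significant <- sp[half][pk] >= peak_factor * stats::median(sp[half]) &&
    n_cross >= 3
  f0 <- freqs[pk]
  # decay guess from the log envelope (peaks of |y|)
  env_idx <- which(diff(sign(diff(abs(y)))) == -2) + 1
  lam0 <- if (length(env_idx) >= 2) {
    stats::coef(stats::lm(log(abs(y[env_idx])) ~ time[env_idx]))[[2]]
  } else 0
  a0 <- max(abs(y)) * exp(-lam0 * time[which.max(abs(y))])

  if (!significant) {
    fit <- tryCatch(
      minpack.lm::nlsLM(z ~ a * exp(l * t),
                        data = data.frame(t = time, z = y),
                        start = list(a = y[1], l = lam0)),
      error = function(e) NULL)
    co <- if (is.null(fit)) c(a = NA_real_, l = lam0) else stats::coef(fit)
    resid <- if (is.null(fit)) NA_real_ else sqrt(mean(stats::resid(fit)^2))
    return(structure(list(decay_rate = unname(co[["l"]]), frequency = 0,
                          amplitude = unname(co[["a"]]), phase = NA_real_,
                          residual = resid, oscillatory = FALSE),
                     class = "an_oscillation_fit"))
  }

  dat <- data.frame(t = time, z = y)
  fit <- minpack.lm::nlsLM(
    z ~ a * exp(l * t) * sin(2 * pi * f * t + phi), data = dat,
    start = list(a = a0, l = lam0, f = f0, phi = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  # canonical form: positive frequency, positive amplitude
  f_hat <- co[["f"]]; a_hat <- co[["a"]]; phi_hat <- co[["phi"]]
  if (f_hat < 0) { f_hat <- -f_hat; phi_hat <- -phi_hat; a_hat <- -a_hat }
  if (a_hat < 0) { a_hat <- -a_hat; phi_hat <- phi_hat + pi }
  phi_hat <- ((phi_hat + pi) %% (2 * pi)) - pi
  structure(list(decay_rate = co[["l"]], frequency = f_hat,
                 amplitude = a_hat, phase = phi_hat,
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 oscillatory = TRUE),
            class = "an_oscillation_fit")
}

#' @export
print.an_oscillation_fit <- function(x, ...) {
  if (x$oscillatory) {
    cat(sprintf("<an_oscillation_fit> decay %.4g, frequency %.4g, RMS residual %.3g\n",
                x$decay_rate, x$frequency, x$residual))
  } else {
    cat(sprintf("<an_oscillation_fit> non-oscillatory; decay %.4g\n",
                x$decay_rate))
  }
  invisible(x)
}

#' Classify the flow state of a trajectory window
#'
#' Heuristic labelling used for branch bookkeeping in ramps and hysteresis
#' loops: \code{quiescent} when the MSV is at numerical zero;
#' \code{chaotic} when the mean stretching number over the window exceeds
#' the estimator resolution \eqn{3/T}; \code{laminar_oscillatory} when the
#' MSV has a significant spectral peak (>= \code{peak_factor} times the
#' median periodogram); \code{laminar_steady} otherwise.
#'
#' @param diagnostics data.frame with \code{time} and \code{msv} columns
#'   (e.g. \code{traj$diagnostics}), spanning at least 0.5 \eqn{\tau_r}.
#' @param alpha Optional stretching-number vector over the same window.
#' @param msv_floor MSV below which the state is quiescent (default
#'   1e-10, in the diagnostics' own units).
#' @param peak_factor Oscillation significance factor (default 5).
#' @param min_span Minimal window length in \eqn{\tau_r} (default 0.5).
#' @return One of "quiescent", "laminar_steady", "laminar_oscillatory",
#'   "chaotic".
#' @export
classify_flow_state <- function(diagnostics, alpha = NULL,
                                msv_floor = 1e-10, peak_factor = 5,
                                min_span = 0.5) {
  stopifnot(is.data.frame(diagnostics), nrow(diagnostics) >= 4)
  span <- diff(range(diagnostics$time))
  if (span < min_span) stop("window too short to classify")
  if (mean(diagnostics$msv) < msv_floor) return("quiescent")
  if (!is.null(alpha) && length(alpha) > 0) {
    if (mean(alpha) > 3 / span) return("chaotic")
  }
  y <- diagnostics$msv - mean(diagnostics$msv)
  if (stats::sd(y) > 1e-12 * mean(diagnostics$msv)) {
    sp <- Mod(stats::fft(y))^2
    half <- 2:(floor(length(y) / 2))
    if (length(half) >= 4 &&
        max(sp[half]) >= peak_factor * stats::median(sp[half]) &&
        stats::sd(y) > 1e-3 * mean(diagnostics$msv)) {
      return("laminar_oscillatory")
    }
  }
  "laminar_steady"
}

#' Count vortices in a flow state
#'
#' Discriminates the laminar attractors (shear, two-vortex, three-vortex,
#' elongated vortices) by counting local extrema of the stream function
#' whose magnitude exceeds \code{floor_frac} of \eqn{\max|\psi|}.
#' A pure shear state has no interior extrema above the floor.
#'
#' @param flow An \code{an_flow}.
#' @param floor_frac Amplitude floor as a fraction of the maximum
#'   (default 0.01).
#' @return Integer count of significant extrema.
#' @export
count_vortices <- function(flow, floor_frac = 0.01) {
  stopifnot(inherits(flow, "an_flow"))
  psi <- flow$psi
  mx <- max(abs(psi))
  if (mx == 0) return(0L)
  up <- shift_mat(psi, -1, 1); dn <- shift_mat(psi, 1, 1)
  lf <- shift_mat(psi, 1, 2); rt <- shift_mat(psi, -1, 2)
  ul <- shift_mat(up, 1, 2); ur <- shift_mat(up, -1, 2)
  dl <- shift_mat(dn, 1, 2); dr <- shift_mat(dn, -1, 2)
  is_max <- psi > up & psi > dn & psi > lf & psi > rt &
    psi > ul & psi > ur & psi > dl & psi > dr
  is_min <- psi < up & psi < dn & psi < lf & psi < rt &
    psi < ul & psi < ur & psi < dl & psi < dr
  sum((is_max | is_min) & abs(psi) > floor_frac * mx)
}
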