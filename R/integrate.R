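#' Integrator configuration
#'
#' Time stepping uses a Peaceman-Rachford alternating-direction-implicit
#' (ADI) scheme on the \eqn{\tau_r}-rescaled director equation: the elastic
#' diffusion term (coefficient exactly 1 in these units, independent of
#' activity) is treated implicitly along one axis per half-step via a
#' periodic (cyclic) tridiagonal solve, while advection and the active
#' source \eqn{-\frac{A}{2}\nabla^2\psi} are explicit. The stream function
#' is recomputed from \eqn{\theta} at the start of each full step and held
#' frozen across both half-steps.
#'
#' @param dt Time step in \eqn{\tau_r}. Default \code{1.8e-5}, the
#'   reference value, kept fixed across activity ramps.
#' @param cfl_warn_threshold Advective CFL number
#'   \eqn{\max|v|\,\Delta t/\Delta x} above which a warning (not an error)
#'   is emitted. Default 1.
#' @return An object of class \code{an_integrator_config}.
#' @export
integrator_config <- function(dt = 1.8e-5, cfl_warn_threshold = 1) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number")
  }
  structure(list(dt = dt, cfl_warn_threshold = cfl_warn_threshold),
            class = "an_integrator_config")
}

#' Noise burst specification
#'
#' Additive Gaussian white noise on the director field, used to generate
#' independent realizations: applied after every time step while
#' \eqn{t <} \code{duration}, after which the evolution is deterministic.
#' The amplitude \code{D} has units \eqn{L^2/\tau_r}; with the space-time
#' white-noise convention adopted here each node receives an independent
#' increment of standard deviation \eqn{\sqrt{2 D \Delta t}/\Delta x},
#' which makes the physical noise level grid-independent. The reference
#' amplitudes are \code{D = 5e-4} for transition-region ensembles and
#' \code{D = 5e-6} for the small bursts used during low-activity ramps.
#'
#' @param D Noise amplitude in \eqn{L^2/\tau_r}, >= 0.
#' @param duration Burst duration in \eqn{\tau_r}.
#' @param seed Optional integer seed consumed by [run_simulation()].
#' @return An object of class \code{an_noise_spec}.
#' @export
noise_spec <- function(D = 5e-4, duration = 1e-2, seed = NULL) {
  if (D < 0) stop("D must be >= 0")
  if (duration < 0) stop("duration must be >= 0")
  structure(list(D = D, duration = duration, seed = seed),
            class = "an_noise_spec")
}

#' Add one step's worth of white noise to the director field
#'
#' @param theta Matrix or \code{an_field}.
#' @param spec [noise_spec()].
#' @param dt Time step in \eqn{\tau_r}.
#' @param grid Matching grid (supplies \eqn{\Delta x}).
#' @return Same type as \code{theta}, with i.i.d. Gaussian increments of
#'   standard deviation \eqn{\sqrt{2 D \Delta t}/\Delta x} per node
#'   (identity when \code{D = 0}). Uses the current RNG stream.
#' @export
inject_noise <- function(theta, spec, dt, grid) {
  stopifnot(inherits(spec, "an_noise_spec"))
  if (spec$D == 0) return(theta)
  sdev <- sqrt(2 * spec$D * dt) / grid$dx
  add <- matrix(stats::rnorm(grid$n^2, sd = sdev), grid$n, grid$n)
  if (inherits(theta, "an_field")) {
    theta$theta <- theta$theta + add
    theta
  } else {
    theta + add
  }
}

#' One ADI step of the director dynamics
#'
#' Advances \eqn{\theta} by a single Peaceman-Rachford step of length
#' \code{config$dt} (in \eqn{\tau_r}). Exposed mainly for testing and for
#' building custom drivers; [run_simulation()] is the usual entry point.
#'
#' @param theta Matrix or \code{an_field}.
#' @param params,grid Model parameters and grid.
#' @param config [integrator_config()].
#' @param flow_on Set \code{FALSE} to suppress the Stokes flow entirely
#'   (pure elastic diffusion), used for scheme-accuracy checks.
#' @return Same type as the input, advanced by \code{dt}.
#' @export
adi_step <- function(theta, params, grid, config = integrator_config(),
                     flow_on = TRUE) {
  stopifnot(inherits(params, "an_params"),
            inherits(config, "an_integrator_config"))
  th <- check_field(theta, grid)
  res <- cpp_evolve(th, params$A, params$R, params$S, config$dt, 1L,
                    sample_every = 0L, flow_on = flow_on)
  if (!res$finite) stop("integration diverged within the step")
  if (inherits(theta, "an_field")) {
    theta$theta <- res$theta
    theta$time <- theta$time + config$dt *
      (if (identical(theta$time_unit, "tau_a")) params$A else 1)
    theta
  } else {
    res$theta
  }
}

#' Run a simulation
#'
#' Evolves the director field for \code{t_final} relaxation times,
#' applying a noise burst for an initial transient when \code{noise} is
#' given, and sampling mean-squared-velocity diagnostics on a fixed
#' cadence. The evolution after the burst is fully deterministic; two runs
#' with the same inputs (and same \code{noise$seed}) are bitwise
#' identical.
#'
#' Times (\code{t_final}, cadences, the trajectory's time axis) are always
#' in \eqn{\tau_r}. Velocity-squared diagnostics are reported in the unit
#' chosen by \code{params$time_unit}.
#'
#' @param initial Initial \code{an_field} (or matrix, taken as t = 0).
#' @param params,grid Model parameters and grid.
#' @param config [integrator_config()].
#' @param noise Optional [noise_spec()]; when present, noise is added after
#'   every step while \eqn{t <} \code{duration}, and \code{noise$seed} (if
#'   non-NULL) seeds the RNG at the start of the run.
#' @param t_final Total integration time in \eqn{\tau_r}.
#' @param sample_every Diagnostic cadence in \eqn{\tau_r} (default 1e-2).
#' @param snapshot_every Snapshot cadence in \eqn{\tau_r}; \code{Inf}
#'   (default) stores only the final state. The reference cadence for
#'   kymographs is 0.1.
#' @param check_resolution Warn if the grid under-resolves the active
#'   length (see [model_params()]); set \code{FALSE} to acknowledge.
#' @return An object of class \code{an_trajectory}: the final field
#'   (\code{$state}), \code{$diagnostics} (data.frame: time, msv, msv_x,
#'   msv_y), \code{$snapshots} + \code{$snapshot_times}, the maximal CFL
#'   number seen (\code{$cfl_max}), and full provenance (\code{$params},
#'   \code{$grid}, \code{$config}, \code{$noise}, \code{$seed}).
#' @examples
#' g <- make_grid(32)
#' p <- model_params(A = 50)
#' tr <- run_simulation(initial_condition(g, "aligned"), p, g,
#'                      t_final = 2e-4, sample_every = 1e-4)
#' tr$diagnostics$msv  # identically zero: uniform state is a fixed point
#' @export
run_simulation <- function(initial, params, grid,
                           config = integrator_config(), noise = NULL,
                           t_final, sample_every = 1e-2,
                           snapshot_every = Inf, check_resolution = TRUE) {
  stopifnot(inherits(params, "an_params"), inherits(grid, "an_grid"),
            inherits(config, "an_integrator_config"))
  if (!is.numeric(t_final) || t_final <= 0) stop("t_final must be > 0")
  check_resolution_guard(grid, params, check_resolution)
  th <- check_field(initial, grid)
  t0 <- if (inherits(initial, "an_field")) {
    initial$time * (if (identical(initial$time_unit, "tau_a")) 1 / params$A else 1)
  } else 0
  dt <- config$dt
  nsteps <- max(1L, as.integer(round(t_final / dt)))
  sample_steps <- max(1L, as.integer(round(sample_every / dt)))
  snap_steps <- if (is.finite(snapshot_every)) {
    max(1L, as.integer(round(snapshot_every / dt)))
  } else NA_integer_
  noise_steps <- 0L
  seed_used <- NULL
  if (!is.null(noise) && noise$D > 0 && noise$duration > 0) {
    stopifnot(inherits(noise, "an_noise_spec"))
    noise_steps <- min(nsteps, as.integer(round(noise$duration / dt)))
    if (!is.null(noise$seed)) {
      set.seed(noise$seed)
      seed_used <- noise$seed
    }
  }

  u2 <- unit_factor(params)^2
  times <- numeric(0); msv_x <- numeric(0); msv_y <- numeric(0)
  snapshots <- list(); snap_times <- numeric(0)
  maxv <- 0
  warned_wind <- FALSE
  step <- 0L

  record_sample <- function(res, base_step) {
    # res carries tau_a-unit MSV samples taken at the start of each step
    if (length(res$sample_steps)) {
      times <<- c(times, t0 + (base_step + res$sample_steps) * dt)
      msv_x <<- c(msv_x, res$msv_x * u2)
      msv_y <<- c(msv_y, res$msv_y * u2)
    }
  }

  advance <- function(th, n_do, base_step, sample_offset) {
    # sample on the global cadence: pass sample_every relative to chunk
    res <- cpp_evolve(th, params$A, params$R, params$S, dt, n_do,
                      sample_every = sample_offset)
    if (!res$finite) {
      stop(sprintf("integration diverged at t = %.6g tau_r",
                   t0 + (base_step + res$steps_done) * dt), call. = FALSE)
    }
    maxv <<- max(maxv, res$maxv)
    record_sample(res, base_step)
    res$theta
  }

  # noise phase: step-by-step with injection after each step
  while (step < noise_steps) {
    do_sample <- if (step %% sample_steps == 0L) 1L else 0L
    th <- advance(th, 1L, step, do_sample)
    th <- inject_noise(th, noise, dt, grid)
    step <- step + 1L
  }
  # deterministic phase, chunked on the sampling and snapshot cadences
  while (step < nsteps) {
    n_do <- min(nsteps - step, sample_steps - (step %% sample_steps))
    if (!is.na(snap_steps)) {
      n_do <- min(n_do, snap_steps - (step %% snap_steps))
    }
    # align chunk starts with the sample cadence
    do_sample <- if (step %% sample_steps == 0L) n_do else 0L
    th <- advance(th, n_do, step, do_sample)
    step <- step + n_do
    if (!is.na(snap_steps) && step %% snap_steps == 0L) {
      snapshots[[length(snapshots) + 1L]] <- th
      snap_times <- c(snap_times, t0 + step * dt)
    }
    if (!warned_wind) {
      jump <- max(abs(th - shift_mat(th, 1, 1)), abs(th - shift_mat(th, 1, 2)))
      if (jump > pi / 2) {
        warning("nearest-neighbour director angle differences exceed pi/2; the field is under-resolved",
                call. = FALSE)
        warned_wind <- TRUE
      }
    }
  }

  # final diagnostic sample from the end state
  fl <- cpp_stream(th, params$A, params$R, params$S)
  times <- c(times, t0 + nsteps * dt)
  msv_x <- c(msv_x, mean(fl$vx^2) * u2)
  msv_y <- c(msv_y, mean(fl$vy^2) * u2)

  cfl <- params$A * maxv * dt / grid$dx  # v in tau_r units vs dt in tau_r
  if (cfl > config$cfl_warn_threshold) {
    warning(sprintf("advective CFL number reached %.2f (threshold %g)",
                    cfl, config$cfl_warn_threshold), call. = FALSE)
  }

  structure(list(
    state = director_field(th, time = (t0 + nsteps * dt) *
                             (if (identical(params$time_unit, "tau_a")) params$A else 1),
                           time_unit = params$time_unit),
    diagnostics = data.frame(time = times, msv = msv_x + msv_y,
                             msv_x = msv_x, msv_y = msv_y),
    snapshots = snapshots, snapshot_times = snap_times,
    params = params, grid = grid, config = config, noise = noise,
    seed = seed_used, cfl_max = cfl, t_final = t_final,
    time_unit_times = "tau_r", time_unit_values = params$time_unit),
    class = "an_trajectory")
}

#' @export
print.an_trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<an_trajectory> A = %g, n = %d, t = %g tau_r, %d samples, final MSV = %.4g (%s units)\n",
              x$params$A, x$grid$n, x$t_final, nrow(d),
              d$msv[nrow(d)], x$time_unit_values))
  invisible(x)
}
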