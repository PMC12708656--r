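#' Activity ramp schedule
#'
#' Quasi-static continuation protocol: the activity is changed in steps,
#' allowing a fixed relaxation time after each increment, and the state of
#' each step seeds the next. Reference schedules: steps of 100 with
#' 2.5 \eqn{\tau_r} relaxation for hysteresis scans of the turbulence
#' transition, and steps of 1 every 2 \eqn{\tau_r} for the slow
#' bifurcation-diagram ramp (with tiny noise bursts, \code{D = 5e-6},
#' below activity 100 to speed up symmetry breaking). Desk-scale runs use
#' coarser schedules; all parameters are exposed.
#'
#' @param A_values Strictly monotone vector of activities, or use
#'   \code{from}/\code{to}/\code{dA}.
#' @param from,to,dA Alternative specification; \code{dA} must be nonzero.
#' @param relax_time Relaxation time per step, \eqn{\tau_r}, > 0.
#' @param noise Optional [noise_spec()] applied at the start of each step.
#' @param noise_below Only apply the per-step burst when A is below this
#'   value (default Inf = always).
#' @return Object of class \code{an_ramp_schedule}.
#' @export
ramp_schedule <- function(A_values = NULL, from = NULL, to = NULL,
                          dA = NULL, relax_time, noise = NULL,
                          noise_below = Inf) {
  if (is.null(A_values)) {
    if (is.null(from) || is.null(to) || is.null(dA)) {
      stop("give either A_values or from/to/dA")
    }
    if (dA == 0) stop("dA must be nonzero")
    if (sign(to - from) != sign(dA)) stop("dA has the wrong sign for from -> to")
    A_values <- seq(from, to, by = dA)
  }
  d <- diff(A_values)
  if (length(A_values) < 1 || any(d == 0) ||
      (any(d > 0) && any(d < 0))) {
    stop("A_values must be strictly monotone")
  }
  if (relax_time <= 0) stop("relax_time must be > 0")
  structure(list(A_values = A_values,
                 relax_time = relax_time,
                 direction = if (length(d) == 0 || all(d > 0)) "up" else "down",
                 noise = noise, noise_below = noise_below),
            class = "an_ramp_schedule")
}

#' Quasi-static activity ramp
#'
#' Runs the continuation protocol defined by a [ramp_schedule()]: at each
#' activity the system relaxes for \code{relax_time} and a branch point is
#' recorded just before the next increment. Branch points carry both the
#' instantaneous final MSV and a tail average (over the trailing
#' \code{settle_frac} of the window, which smooths limit-cycle states),
#' plus the MSV growth factor across the window -- the detector used to
#' locate instabilities of the current branch.
#'
#' @param initial Starting field (matrix or \code{an_field}).
#' @param schedule [ramp_schedule()].
#' @param params Template [model_params()] supplying R, S and the unit;
#'   the schedule overrides A.
#' @param grid,config Grid and integrator configuration.
#' @param sample_every Diagnostic cadence within each step, \eqn{\tau_r}.
#' @param settle_frac Fraction of each window averaged into the recorded
#'   branch MSV (default 0.25).
#' @param seed Optional integer; per-step burst seeds are derived from it
#'   by a counter so every step's noise is reproducible.
#' @param check_resolution See [run_simulation()].
#' @param progress Print one line per step.
#' @return Object of class \code{an_branch}: \code{$points} (data.frame
#'   with A, tail-averaged msv/msv_x/msv_y, the final-sample msv_end, the
#'   within-window growth factors of the total and transverse MSV, and the
#'   peak CFL number), \code{$state} (final field), and provenance.
#' @export
activity_ramp <- function(initial, schedule, params, grid,
                          config = integrator_config(),
                          sample_every = 1e-2, settle_frac = 0.25,
                          seed = NULL, check_resolution = TRUE,
                          progress = FALSE) {
  stopifnot(inherits(schedule, "an_ramp_schedule"),
            inherits(params, "an_params"))
  th <- check_field(initial, grid)
  pts <- vector("list", length(schedule$A_values))
  for (i in seq_along(schedule$A_values)) {
    A <- schedule$A_values[i]
    p <- model_params(A, params$R, params$S, params$time_unit)
    ns <- NULL
    if (!is.null(schedule$noise) && A < schedule$noise_below) {
      ns <- schedule$noise
      ns$seed <- if (!is.null(seed)) seed + i else ns$seed
    }
    tr <- run_simulation(director_field(th), p, grid, config, noise = ns,
                         t_final = schedule$relax_time,
                         sample_every = sample_every,
                         check_resolution = check_resolution)
    th <- tr$state$theta
    d <- tr$diagnostics
    tail_idx <- which(d$time - d$time[1] >=
                        (1 - settle_frac) * schedule$relax_time)
    half <- nrow(d) %/% 2
    growth_y <- if (half >= 1 && d$msv_y[half] > 0) {
      d$msv_y[nrow(d)] / d$msv_y[half]
    } else NA_real_
    growth <- if (half >= 1 && d$msv[half] > 0) {
      d$msv[nrow(d)] / d$msv[half]
    } else NA_real_
    pts[[i]] <- data.frame(
      A = A,
      msv = mean(d$msv[tail_idx]),
      msv_x = mean(d$msv_x[tail_idx]),
      msv_y = mean(d$msv_y[tail_idx]),
      msv_end = d$msv[nrow(d)],
      growth = growth,
      growth_y = growth_y,
      cfl = tr$cfl_max)
    if (progress) {
      message(sprintf("A = %g: msv = %.4g (x %.3g / y %.3g)", A,
                      pts[[i]]$msv, pts[[i]]$msv_x, pts[[i]]$msv_y))
    }
  }
  structure(list(points = do.call(rbind, pts),
                 state = director_field(th),
                 schedule = schedule, params = params, grid = grid,
                 config = config, seed = seed),
            class = "an_branch")
}

#' @export
print.an_branch <- function(x, ...) {
  cat(sprintf("<an_branch> %s ramp, A in [%g, %g], %d points\n",
              x$schedule$direction, min(x$points$A), max(x$points$A),
              nrow(x$points)))
  invisible(x)
}

#' Hysteresis loop across a subcritical transition
#'
#' Composes an upward and a downward [activity_ramp()] sharing the
#' turning-point state, and locates the discontinuous jumps on each
#' branch: the first step at which the MSV or either of its components
#' changes by more than \code{jump_threshold} relative to the previous
#' step (default 50%; coarse desk-scale loops across weaker transitions
#' use smaller thresholds). In a bistable window the up-jump
#' occurs at strictly higher activity than the down-jump; coinciding
#' branches (no jumps) indicate a single attractor over the range.
#'
#' @param initial State on the lower branch at \code{A_min}.
#' @param A_min,A_max Loop range, \code{A_min < A_max}.
#' @param dA Step size (> 0; the down branch uses \code{-dA}).
#' @param relax Relaxation time per step, \eqn{\tau_r}.
#' @param params,grid,config As in [activity_ramp()].
#' @param noise Optional per-step [noise_spec()].
#' @param jump_threshold Relative MSV change declaring a jump.
#' @param ... Passed to [activity_ramp()].
#' @return List with \code{$up}, \code{$down} (an_branch),
#'   \code{$up_jump}, \code{$down_jump} (activity at which the new state
#'   first appears; NA when no jump detected).
#' @export
hysteresis_loop <- function(initial, A_min, A_max, dA, relax, params, grid,
                            config = integrator_config(), noise = NULL,
                            jump_threshold = 0.5, ...) {
  if (!(A_min < A_max)) stop("need A_min < A_max")
  if (dA <= 0) stop("dA must be > 0")
  up <- activity_ramp(initial,
                      ramp_schedule(from = A_min, to = A_max, dA = dA,
                                    relax_time = relax, noise = noise),
                      params, grid, config, ...)
  down <- activity_ramp(up$state,
                        ramp_schedule(from = A_max, to = A_min, dA = -dA,
                                      relax_time = relax, noise = noise),
                        params, grid, config, ...)
  list(up = up, down = down,
       up_jump = detect_jump(up$points, jump_threshold),
       down_jump = detect_jump(down$points, jump_threshold))
}

# internal: first activity at which the MSV or either of its components
# changes by more than `threshold` relative to the previous step.  The
# subcritical vortex transitions rearrange the flow pattern, so the x and
# y components jump far more sharply than their sum.
detect_jump <- function(points, threshold = 0.5) {
  if (nrow(points) < 2) return(NA_real_)
  rel <- sapply(c("msv", "msv_x", "msv_y"), function(col) {
    m <- points[[col]]
    abs(diff(m)) / pmax(m[-length(m)], .Machine$double.xmin)
  })
  worst <- apply(as.matrix(rel), 1, max)
  i <- which(worst > threshold)
  if (length(i) == 0) NA_real_ else points$A[i[1] + 1]
}

#' Ensemble scan of the transition to turbulence
#'
#' The statistical protocol behind the transition diagnostics: at each
#' activity, independent realizations start from the aligned state, are
#' decorated by a short noise burst (default \code{D = 5e-4} for
#' \eqn{10^{-2}\tau_r}), then evolve deterministically while the deviation
#' dynamics are tracked. Per activity the scan reports ensemble statistics
#' of the MSV and the maximal Lyapunov exponent, the pooled
#' stretching-number sample, and the chaotic fraction \eqn{f_c}.
#'
#' Reference ensemble sizes are 32 realizations (64 from the onset of the
#' transition region, \eqn{A \ge 3800}) and integration times of
#' 600 \eqn{\tau_r} (10 below \eqn{A = 3000}); those defaults apply when
#' \code{n_realizations}/\code{t_f} are NULL, but desk-scale work passes
#' explicit smaller values.
#'
#' @param A_values Activities to scan.
#' @param params Template [model_params()] (R, S, unit).
#' @param grid,config Grid and integrator configuration.
#' @param n_realizations Realizations per activity (NULL = reference rule).
#' @param t_f Post-burst integration time, \eqn{\tau_r} (NULL = reference
#'   rule).
#' @param noise Burst specification, default \code{noise_spec(5e-4, 1e-2)}.
#' @param lyap [lyapunov_config()] for the deviation tracking.
#' @param master_seed Integer; per-realization seeds are
#'   \code{master_seed + 1000 * i_A + r} (a counter scheme recorded in the
#'   output).
#' @param check_resolution See [run_simulation()].
#' @param progress Print progress lines.
#' @return List of class \code{an_ensemble_scan}: \code{$table}
#'   (per-activity data.frame: A, n, msv_mean, msv_sem, mle_mean,
#'   mle_sem, f_c), \code{$alphas} (named list of pooled stretching
#'   numbers), \code{$realizations} (nested per-A list with each
#'   realization's MLE, final MSV, seed, and any failure message).
#' @export
ensemble_transition_scan <- function(A_values, params, grid,
                                     config = integrator_config(),
                                     n_realizations = NULL, t_f = NULL,
                                     noise = noise_spec(5e-4, 1e-2),
                                     lyap = lyapunov_config(),
                                     master_seed = 1,
                                     check_resolution = TRUE,
                                     progress = FALSE) {
  stopifnot(inherits(params, "an_params"))
  rows <- list(); alphas <- list(); reals <- list()
  for (ia in seq_along(A_values)) {
    A <- A_values[ia]
    p <- model_params(A, params$R, params$S, params$time_unit)
    nr <- if (is.null(n_realizations)) (if (A >= 3800) 64L else 32L)
          else n_realizations
    tf <- if (is.null(t_f)) (if (A < 3000) 10 else 600) else t_f
    res_A <- vector("list", nr)
    pool <- numeric(0)
    for (r in seq_len(nr)) {
      sd_r <- master_seed + 1000L * ia + r
      res_A[[r]] <- tryCatch({
        ns <- noise; ns$seed <- sd_r
        burst <- run_simulation(initial_condition(grid, "aligned"), p, grid,
                                config, noise = ns, t_final = ns$duration,
                                sample_every = ns$duration,
                                check_resolution = check_resolution)
        run <- evolve_with_deviation(burst$state, p, grid, config, lyap,
                                     t_total = tf, seed = sd_r,
                                     sample_msv_every = min(0.1, tf),
                                     check_resolution = FALSE)
        a <- stretching_series(run)$alpha
        pool <- c(pool, a)
        list(mle = mle(run), msv_final = run$msv$msv[nrow(run$msv)],
             seed = sd_r, error = NULL)
      }, error = function(e) list(mle = NA_real_, msv_final = NA_real_,
                                  seed = sd_r, error = conditionMessage(e)))
      if (progress) {
        message(sprintf("A = %g realization %d/%d: MLE = %.4g", A, r, nr,
                        res_A[[r]]$mle))
      }
    }
    mles <- vapply(res_A, `[[`, numeric(1), "mle")
    msvs <- vapply(res_A, `[[`, numeric(1), "msv_final")
    fc <- if (length(pool)) chaotic_fraction(pool)$f_c else NA_real_
    rows[[ia]] <- data.frame(
      A = A, n = nr, t_f = tf,
      msv_mean = mean(msvs, na.rm = TRUE),
      msv_sem = stats::sd(msvs, na.rm = TRUE) / sqrt(sum(is.finite(msvs))),
      mle_mean = mean(mles, na.rm = TRUE),
      mle_sem = stats::sd(mles, na.rm = TRUE) / sqrt(sum(is.finite(mles))),
      f_c = fc)
    alphas[[as.character(A)]] <- pool
    reals[[as.character(A)]] <- res_A
  }
  structure(list(table = do.call(rbind, rows), alphas = alphas,
                 realizations = reals, master_seed = master_seed,
                 seed_scheme = "master_seed + 1000 * activity_index + realization"),
            class = "an_ensemble_scan")
}

#' @export
print.an_ensemble_scan <- function(x, ...) {
  cat("<an_ensemble_scan>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
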