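#' Lyapunov analysis configuration
#'
#' Chaos is quantified by evolving one or more shadow trajectories
#' \eqn{\tilde\theta^{(l)} = \theta + w^{(l)}} through the full nonlinear
#' map alongside the reference, and monitoring the growth of the deviations
#' \eqn{w^{(l)}}. Every \code{renorm_interval} the deviations are
#' Gram-Schmidt orthonormalized (for \code{m > 1}) and rescaled back to
#' Euclidean norm \code{norm0}; the logged growth factors accumulate into
#' finite-time Lyapunov exponents. The defaults are the reference values:
#' rescale to \eqn{10^{-6}} every \eqn{10^{-3}\tau_r}, stretching-number
#' windows of \eqn{5\times10^{-3}\tau_r}. Results are insensitive to the
#' rescaling parameters within reason.
#'
#' @param norm0 Deviation norm after each renormalization.
#' @param renorm_interval Time between renormalizations, \eqn{\tau_r}.
#'   Internally rounded to a whole number of steps.
#' @param window Stretching-number window, \eqn{\tau_r}; must be an
#'   integer multiple of \code{renorm_interval}.
#' @param m Number of deviation vectors (= exponents computed), >= 1.
#' @return An object of class \code{an_lyapunov_config}.
#' @export
lyapunov_config <- function(norm0 = 1e-6, renorm_interval = 1e-3,
                            window = 5e-3, m = 1) {
  if (norm0 <= 0) stop("norm0 must be > 0")
  if (renorm_interval <= 0) stop("renorm_interval must be > 0")
  ratio <- window / renorm_interval
  if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1) {
    stop("window must be a positive integer multiple of renorm_interval")
  }
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  structure(list(norm0 = norm0, renorm_interval = renorm_interval,
                 window = window, m = as.integer(m)),
            class = "an_lyapunov_config")
}

#' Evolve a reference trajectory with deviation vectors
#'
#' The work-horse of the Lyapunov module. Starting from \code{initial},
#' the reference field and \code{lyap$m} perturbed companions are advanced
#' with the same deterministic integrator; every renormalization interval
#' the deviations \eqn{w^{(l)} = \tilde\theta^{(l)} - \theta} are
#' orthonormalized and rescaled to \code{norm0}, and the log growth factors
#' are recorded. The reference evolution is bitwise independent of
#' \code{m}.
#'
#' Initial deviations are drawn from a normal distribution (scaled and
#' orthonormalized) unless \code{init_deviations} supplies explicit
#' fields, e.g. a single Fourier mode for linear-regime checks.
#'
#' @param initial Starting \code{an_field} or matrix.
#' @param params,grid,config Model parameters, grid, integrator config.
#' @param lyap [lyapunov_config()].
#' @param t_total Integration time in \eqn{\tau_r}.
#' @param seed Optional integer seed for the initial deviations.
#' @param init_deviations Optional list of \code{m} matrices used (after
#'   orthonormalization and rescaling) as initial deviations.
#' @param sample_msv_every Optional cadence (\eqn{\tau_r}) at which MSV of
#'   the reference is recorded alongside the exponents.
#' @param check_resolution See [run_simulation()].
#' @return An object of class \code{an_lyapunov_run}: \code{$increments}
#'   (matrix, one row per renormalization, one column per deviation, log
#'   growth factors), \code{$interval} (the realized renormalization
#'   interval in \eqn{\tau_r}), \code{$times}, \code{$state} (final
#'   reference field), \code{$deviations} (final orthogonalized deviation
#'   vectors, columns of norm \code{norm0}), \code{$msv} (data.frame or
#'   NULL), plus provenance.
#' @export
evolve_with_deviation <- function(initial, params, grid,
                                  config = integrator_config(),
                                  lyap = lyapunov_config(), t_total,
                                  seed = NULL, init_deviations = NULL,
                                  sample_msv_every = NULL,
                                  check_resolution = TRUE) {
  stopifnot(inherits(lyap, "an_lyapunov_config"),
            inherits(config, "an_integrator_config"))
  check_resolution_guard(grid, params, check_resolution)
  th <- check_field(initial, grid)
  n <- grid$n
  m <- lyap$m
  dt <- config$dt
  steps_per <- max(1L, as.integer(round(lyap$renorm_interval / dt)))
  interval <- steps_per * dt
  n_renorm <- max(1L, as.integer(round(t_total / interval)))

  if (!is.null(seed)) set.seed(seed)
  W <- if (is.null(init_deviations)) {
    matrix(stats::rnorm(n * n * m), n * n, m)
  } else {
    stopifnot(length(init_deviations) == m)
    vapply(init_deviations, function(w) as.numeric(check_field(w, grid)),
           numeric(n * n))
  }
  W <- gram_schmidt(matrix(W, n * n, m)) * lyap$norm0

  increments <- matrix(NA_real_, n_renorm, m)
  msv_rows <- NULL
  msv_every_renorms <- if (!is.null(sample_msv_every)) {
    max(1L, as.integer(round(sample_msv_every / interval)))
  } else NA_integer_
  u2 <- unit_factor(params)^2
  step_field <- function(f, nst) {
    res <- cpp_evolve(f, params$A, params$R, params$S, dt, nst)
    if (!res$finite) stop("integration diverged during Lyapunov run",
                          call. = FALSE)
    res$theta
  }

  warned_short <- FALSE
  for (r in seq_len(n_renorm)) {
    th_ref_old <- th
    th <- step_field(th, steps_per)
    newW <- matrix(0, n * n, m)
    logs <- numeric(m)
    ok <- TRUE
    for (l in seq_len(m)) {
      comp <- step_field(th_ref_old + matrix(W[, l], n, n), steps_per)
      w <- as.numeric(comp - th)
      if (!all(is.finite(w))) { ok <- FALSE; break }
      if (l > 1) {
        proj <- crossprod(newW[, seq_len(l - 1), drop = FALSE], w)
        w <- w - newW[, seq_len(l - 1), drop = FALSE] %*% proj
      }
      nw <- sqrt(sum(w^2))
      if (!is.finite(nw) || nw == 0) { ok <- FALSE; break }
      logs[l] <- log(nw / lyap$norm0)
      newW[, l] <- w / nw
    }
    if (!ok) {
      # deviation overflowed within the interval: redo with sub-intervals
      if (!warned_short) {
        warning("deviation grew beyond representable range within a renormalization interval; subdividing",
                call. = FALSE)
        warned_short <- TRUE
      }
      sub <- 8L
      sub_steps <- diff(round(seq(0, steps_per, length.out = sub + 1)))
      th_s <- th_ref_old
      logs <- numeric(m)
      for (ss in sub_steps[sub_steps > 0]) {
        th_new <- step_field(th_s, ss)
        for (l in seq_len(m)) {
          comp <- step_field(th_s + matrix(W[, l], n, n), ss)
          w <- as.numeric(comp - th_new)
          if (l > 1) {
            prev <- matrix(W[, seq_len(l - 1), drop = FALSE] /
                             lyap$norm0, n * n)
            w <- w - prev %*% crossprod(prev, w)
          }
          nw <- sqrt(sum(w^2))
          logs[l] <- logs[l] + log(nw / lyap$norm0)
          W[, l] <- w * (lyap$norm0 / nw)
        }
        th_s <- th_new
      }
      th <- th_s
      increments[r, ] <- logs
      next
    }
    increments[r, ] <- logs
    W <- newW * lyap$norm0
    if (!is.na(msv_every_renorms) && r %% msv_every_renorms == 0L) {
      fl <- cpp_stream(th, params$A, params$R, params$S)
      msv_rows <- rbind(msv_rows,
                        c(r * interval, mean(fl$vx^2) * u2, mean(fl$vy^2) * u2))
    }
  }

  msv <- if (!is.null(msv_rows)) {
    data.frame(time = msv_rows[, 1], msv = msv_rows[, 2] + msv_rows[, 3],
               msv_x = msv_rows[, 2], msv_y = msv_rows[, 3])
  } else NULL
  structure(list(increments = increments, interval = interval,
                 times = seq_len(n_renorm) * interval, m = m,
                 norm0 = lyap$norm0, window = lyap$window,
                 state = director_field(th, time = n_renorm * interval),
                 deviations = W, msv = msv, params = params, grid = grid,
                 config = config, seed = seed),
            class = "an_lyapunov_run")
}

#' @export
print.an_lyapunov_run <- function(x, ...) {
  cat(sprintf("<an_lyapunov_run> A = %g, n = %d, T = %g tau_r, m = %d, MLE = %.4g / tau_r\n",
              x$params$A, x$grid$n, max(x$times), x$m, mle(x)))
  invisible(x)
}

# internal: orthonormalize columns (classical Gram-Schmidt, as used in the
# renormalization loop)
gram_schmidt <- function(W) {
  for (l in seq_len(ncol(W))) {
    w <- W[, l]
    if (l > 1) {
      prev <- W[, seq_len(l - 1), drop = FALSE]
      w <- w - prev %*% crossprod(prev, w)
    }
    W[, l] <- w / sqrt(sum(w^2))
  }
  W
}

#' Maximal Lyapunov exponent from accumulated growth
#'
#' The finite-time estimate of the maximal Lyapunov exponent:
#' \eqn{\Lambda = \frac{1}{T}\sum_k \log(\|w(t_k)\| / \|w(t_{k-1})\|)},
#' i.e. the total accumulated log growth of the leading deviation divided
#' by the integration time. Positive values indicate chaos; regular
#' dynamics give zero (within estimator resolution \eqn{\sim 3/T}) or
#' negative values. Identical, by construction, to the time average of the
#' stretching numbers over the same run.
#'
#' @param x An \code{an_lyapunov_run}, or a numeric vector of log-growth
#'   increments.
#' @param total_time Required when \code{x} is a vector: the total time
#'   spanned, \eqn{\tau_r}.
#' @return \eqn{\Lambda} in \eqn{1/\tau_r}.
#' @export
mle <- function(x, total_time = NULL) {
  if (inherits(x, "an_lyapunov_run")) {
    inc <- x$increments[, 1]
    total_time <- nrow(x$increments) * x$interval
  } else {
    inc <- as.numeric(x)
    if (is.null(total_time) || total_time <= 0) {
      stop("total_time must be given (and > 0) for a raw increment vector")
    }
  }
  if (length(inc) == 0) stop("no growth increments recorded")
  sum(inc) / total_time
}

#' Stretching numbers (finite-time Lyapunov exponents)
#'
#' Growth rates of the leading deviation over consecutive windows:
#' \eqn{\alpha_k = \frac{1}{t_k - t_{k-1}}
#'   \log(\|w(t_k)\|/\|w(t_{k-1})\|)}. Windows tile the run; a partial
#' trailing window is dropped with a warning. The time series of
#' \eqn{\alpha} distinguishes chaotic episodes (\eqn{\alpha > 0}) from
#' laminar ones (\eqn{\alpha \approx 0}) within a single realization.
#'
#' @param run An \code{an_lyapunov_run}.
#' @param window Window length in \eqn{\tau_r}; defaults to the run's
#'   configured window. Must be an integer multiple of the realized
#'   renormalization interval.
#' @return data.frame with columns \code{t_start}, \code{t_end},
#'   \code{alpha} (\eqn{1/\tau_r}).
#' @export
stretching_series <- function(run, window = NULL) {
  stopifnot(inherits(run, "an_lyapunov_run"))
  if (is.null(window)) window <- run$window
  # the realized interval is a whole number of steps, so a nominal window
  # is honoured as the nearest whole number of renormalization intervals
  ratio <- window / run$interval
  k <- as.integer(round(ratio))
  if (k < 1 || abs(ratio - k) > 0.2 * k) {
    stop("window must be a positive integer multiple of the renormalization interval")
  }
  inc <- run$increments[, 1]
  n_full <- length(inc) %/% k
  if (n_full == 0) stop("run shorter than one stretching window")
  if (length(inc) %% k != 0) {
    warning(sprintf("dropping partial trailing window (%d of %d increments)",
                    length(inc) - n_full * k, length(inc)), call. = FALSE)
  }
  idx <- seq_len(n_full * k)
  alpha <- colSums(matrix(inc[idx], k, n_full)) / (k * run$interval)
  data.frame(t_start = (seq_len(n_full) - 1) * k * run$interval,
             t_end = seq_len(n_full) * k * run$interval,
             alpha = alpha)
}

#' Lyapunov spectrum of a state
#'
#' Ordered finite-time estimates \eqn{\lambda_1 \ge \dots \ge \lambda_m}
#' from a multi-deviation run (Gram-Schmidt / Benettin method):
#' \eqn{\lambda_l} is the time-averaged log growth of the l-th
#' orthonormalized deviation. \eqn{\lambda_1} coincides with [mle()] on
#' the same run. Vanishing exponents signal Goldstone modes of broken
#' continuous symmetries (one per broken translation), and degenerate
#' negative pairs signal complex-conjugate eigenvalues, i.e. decaying
#' oscillations.
#'
#' @param run An \code{an_lyapunov_run} with \code{m >= 1}.
#' @param drift_tol Convergence check: warn if any exponent estimated from
#'   the last quarter of the run differs from the full-run estimate by
#'   more than \code{drift_tol} times \eqn{3/T} (the estimator
#'   resolution). Default 2.
#' @return Object of class \code{an_lyapunov_spectrum}: \code{$lambda}
#'   (sorted descending, \eqn{1/\tau_r}), \code{$T}, \code{$converged}.
#' @export
lyapunov_spectrum <- function(run, drift_tol = 2) {
  stopifnot(inherits(run, "an_lyapunov_run"))
  T_tot <- nrow(run$increments) * run$interval
  lam <- colSums(run$increments) / T_tot
  q <- nrow(run$increments) %/% 4
  converged <- TRUE
  if (q >= 2) {
    tail_idx <- (nrow(run$increments) - q + 1):nrow(run$increments)
    lam_tail <- colSums(run$increments[tail_idx, , drop = FALSE]) /
      (q * run$interval)
    res <- 3 / T_tot
    if (any(abs(lam_tail - lam) > drift_tol * pmax(res, abs(lam) * 0.5))) {
      converged <- FALSE
      warning("Lyapunov spectrum may not be converged (last-quarter drift)",
              call. = FALSE)
    }
  }
  structure(list(lambda = sort(lam, decreasing = TRUE), T = T_tot,
                 converged = converged, m = run$m),
            class = "an_lyapunov_spectrum")
}

#' @export
print.an_lyapunov_spectrum <- function(x, ...) {
  cat(sprintf("<an_lyapunov_spectrum> T = %g tau_r: %s\n", x$T,
              paste(sprintf("%.4g", x$lambda), collapse = ", ")))
  invisible(x)
}

#' Chaotic fraction from pooled stretching numbers
#'
#' The order parameter of the transition to turbulence: the fraction of
#' time the system spends in the chaotic state, extracted from the pooled
#' histogram of stretching numbers of an ensemble. The distribution is
#' kernel-smoothed (Gaussian kernel, Silverman-style default bandwidth);
#' when it is bimodal -- a laminar peak at \eqn{\alpha \approx 0} and a
#' chaotic peak at positive \eqn{\alpha} -- the separation threshold is
#' placed at the density minimum between the two peaks and \eqn{f_c} is
#' the probability mass above it. A distribution unimodal at zero gives
#' \eqn{f_c = 0}; unimodal at positive \eqn{\alpha} gives \eqn{f_c = 1}.
#'
#' @param alpha Numeric vector (or list of vectors, pooled) of stretching
#'   numbers in \eqn{1/\tau_r}.
#' @param min_peak_frac Local maxima of the smoothed density below this
#'   fraction of the global maximum are ignored (default 0.05).
#' @return List with \code{f_c}, \code{threshold} (NA when unimodal),
#'   \code{bandwidth}, and the peak locations \code{peaks}.
#' @examples
#' chaotic_fraction(rnorm(500, 0, 0.3))$f_c                    # 0
#' chaotic_fraction(c(rnorm(300, 0, 0.3), rnorm(300, 30, 1)))$f_c  # ~0.5
#' @export
chaotic_fraction <- function(alpha, min_peak_frac = 0.05) {
  if (is.list(alpha)) alpha <- unlist(alpha, use.names = FALSE)
  alpha <- alpha[is.finite(alpha)]
  if (length(alpha) == 0) stop("empty stretching-number ensemble")
  if (stats::sd(alpha) == 0) {
    # degenerate: a point mass
    return(list(f_c = if (abs(alpha[1]) < .Machine$double.eps^0.5) 0 else
                  as.numeric(alpha[1] > 0),
                threshold = NA_real_, bandwidth = 0, peaks = alpha[1]))
  }
  d <- stats::density(alpha)
  y <- d$y; x <- d$x
  is_pk <- which(diff(sign(diff(y))) == -2) + 1
  is_pk <- is_pk[y[is_pk] >= min_peak_frac * max(y)]
  if (length(is_pk) == 0) is_pk <- which.max(y)
  pk_x <- x[is_pk]
  # zero tolerance: twice the bandwidth plus the KDE grid resolution
  # (heavy-tailed samples stretch the grid, displacing a peak at zero)
  zero_tol <- 2 * d$bw + diff(x[1:2])
  # the laminar peak must itself sit at alpha ~ 0
  near0 <- which(abs(pk_x) <= zero_tol)
  if (length(near0) == 0) {
    # no laminar peak: the distribution lives away from zero
    f_c <- if (all(pk_x > 0)) 1 else if (all(pk_x < 0)) 0 else
      mean(alpha > 0)
    return(list(f_c = f_c, threshold = NA_real_, bandwidth = d$bw,
                peaks = pk_x))
  }
  lam_x <- pk_x[near0[which.min(abs(pk_x[near0]))]]
  # chaotic candidates: peaks at clearly positive alpha beyond the
  # laminar one (a second peak at more-negative alpha is still laminar)
  pos <- is_pk[pk_x > max(lam_x, 0) + zero_tol]
  if (length(pos) == 0) {
    return(list(f_c = 0, threshold = NA_real_, bandwidth = d$bw,
                peaks = pk_x))
  }
  chaos_i <- pos[which.max(y[pos])]
  between <- which(x > lam_x & x < x[chaos_i])
  thr <- x[between[which.min(y[between])]]
  list(f_c = mean(alpha > thr), threshold = thr, bandwidth = d$bw,
       peaks = pk_x)
}
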