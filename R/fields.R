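#' Director angle field
#'
#' The sole dynamical state of the model: the director angle
#' \eqn{\theta(\mathbf{r}, t)} on the periodic grid, stored as an unwrapped
#' real field (the director is \eqn{\mathbf{n} = (\cos\theta, \sin\theta)}).
#' The system is deep in the nematic phase and defect-free, so no winding
#' handling is applied; see [run_simulation()] for the under-resolution
#' warning emitted when neighbouring angles jump by more than \eqn{\pi/2}.
#'
#' @param theta Numeric n-by-n matrix of angles (radians). Rows index x,
#'   columns index y.
#' @param time Time stamp of the field, in \code{time_unit}.
#' @param time_unit "tau_r" or "tau_a".
#' @return An object of class \code{an_field}.
#' @export
director_field <- function(theta, time = 0, time_unit = "tau_r") {
  theta <- as.matrix(theta)
  if (nrow(theta) != ncol(theta)) stop("theta must be square")
  if (!all(is.finite(theta))) stop("theta must be finite everywhere")
  structure(list(theta = theta, time = time, time_unit = time_unit),
            class = "an_field")
}

#' @export
print.an_field <- function(x, ...) {
  cat(sprintf("<an_field> %d x %d director angles, t = %g %s, range [%.4g, %.4g]\n",
              nrow(x$theta), ncol(x$theta), x$time, x$time_unit,
              min(x$theta), max(x$theta)))
  invisible(x)
}

#' Initial conditions for simulations
#'
#' Generates the director fields from which all protocols start.
#'
#' \describe{
#'   \item{aligned}{Uniform alignment along x: \eqn{\theta \equiv 0}. The
#'     exact fixed point of the dynamics.}
#'   \item{aligned_noise}{Aligned plus i.i.d. Gaussian angles of standard
#'     deviation \code{sd}. Note that the ensemble protocols instead break
#'     symmetry with a dynamic noise burst ([noise_spec()]); this static
#'     variant is mainly for quick experiments.}
#'   \item{single_mode}{\eqn{\theta = \varepsilon \sin(2\pi(m_x x + m_y y)
#'     + \phi)}: a single Fourier mode, the input for linear-theory checks.
#'     \code{mode} gives the integer mode numbers \eqn{(m_x, m_y)}; the
#'     physical wavevector is \eqn{2\pi(m_x, m_y)}.}
#'   \item{random_smooth}{Gaussian random field low-pass filtered to mode
#'     numbers below \code{kcut_index}, rescaled to RMS \code{amplitude}.}
#' }
#'
#' @param grid An [make_grid()] object.
#' @param kind One of "aligned", "aligned_noise", "single_mode",
#'   "random_smooth".
#' @param amplitude Mode amplitude \eqn{\varepsilon} (single_mode) or target
#'   RMS (random_smooth).
#' @param mode Integer vector c(mx, my) for single_mode.
#' @param phase Phase \eqn{\phi} for single_mode.
#' @param sd Standard deviation for aligned_noise.
#' @param kcut_index Mode-number cutoff for random_smooth (default n/8).
#' @param seed Optional integer; when given, the RNG is seeded locally so
#'   the same call reproduces the same field without touching the caller's
#'   RNG stream.
#' @return An \code{an_field} at time 0 (tau_r).
#' @examples
#' g <- make_grid(64)
#' ic <- initial_condition(g, "single_mode", amplitude = 1e-6, mode = c(0, 1))
#' max(abs(ic$theta))  # 1e-6
#' @export
initial_condition <- function(grid,
                              kind = c("aligned", "aligned_noise",
                                       "single_mode", "random_smooth"),
                              amplitude = 1e-6, mode = c(1, 0), phase = 0,
                              sd = 1e-3, kcut_index = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "an_grid"))
  n <- grid$n
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  theta <- switch(kind,
    aligned = matrix(0, n, n),
    aligned_noise = matrix(stats::rnorm(n * n, sd = sd), n, n),
    single_mode = {
      if (any(mode != round(mode))) {
        stop("mode numbers must be integers on the periodic grid")
      }
      if (amplitude <= 0) stop("amplitude must be positive")
      ph <- outer(grid$x, grid$y, function(x, y) {
        2 * pi * (mode[1] * x + mode[2] * y) + phase
      })
      amplitude * sin(ph)
    },
    random_smooth = {
      if (is.null(kcut_index)) kcut_index <- n / 8
      z <- matrix(stats::rnorm(n * n), n, n)
      zh <- stats::fft(z)
      f <- c(0:(n %/% 2), (n %/% 2 - n + 1):-1)
      keep <- outer(abs(f) < kcut_index, abs(f) < kcut_index, `&`)
      th <- Re(stats::fft(zh * keep, inverse = TRUE)) / (n * n)
      th * amplitude / sqrt(mean(th^2))
    })
  director_field(theta, time = 0)
}
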