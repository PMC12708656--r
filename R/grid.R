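#' Periodic grid for the unit square
#'
#' Builds the spatial discretization used by all solvers: an \code{n} by
#' \code{n} doubly periodic grid on the unit square (system size L = 1), its
#' per-axis angular wavenumbers, and the 2/3-rule anti-aliasing mask applied
#' to the right-hand side of the spectral Stokes solve.
#'
#' @param n Number of grid points per side. Must be even and at least 16.
#'   The reference resolution is 256.
#' @return An object of class \code{an_grid}: a list with elements
#'   \code{n}, \code{dx} (= 1/n), \code{x} and \code{y} (node coordinates),
#'   \code{kx} and \code{ky} (per-axis wavenumbers, multiples of 2\eqn{\pi}),
#'   and \code{dealias} (logical matrix, TRUE for retained modes).
#' @examples
#' g <- make_grid(64)
#' g$dx            # 1/64
#' range(g$kx)     # +/- 2*pi*32
#' @export
make_grid <- function(n = 256) {
  if (length(n) != 1 || !is.finite(n) || n != round(n)) {
    stop("n must be a single integer")
  }
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("n must be even")
  if (n < 16L) stop("n must be at least 16")
  f <- c(0:(n %/% 2), (n %/% 2 - n + 1):-1)  # 0, 1, ..., n/2, -(n/2-1), ..., -1
  k <- 2 * pi * f
  keep <- abs(f) < n / 3
  g <- list(
    n = n,
    dx = 1 / n,
    x = (0:(n - 1)) / n,
    y = (0:(n - 1)) / n,
    kx = k,
    ky = k,
    dealias = outer(keep, keep, `&`)
  )
  class(g) <- "an_grid"
  g
}

#' @export
print.an_grid <- function(x, ...) {
  cat(sprintf("<an_grid> %d x %d periodic unit square, dx = 1/%d, 2/3 dealias (%d modes kept)\n",
              x$n, x$n, x$n, sum(x$dealias)))
  invisible(x)
}

# internal: check a field matrix against a grid
check_field <- function(theta, grid) {
  th <- as_theta_matrix(theta)
  if (nrow(th) != grid$n || ncol(th) != grid$n) {
    stop("field shape does not match grid")
  }
  if (!all(is.finite(th))) stop("field contains non-finite values")
  th
}

as_theta_matrix <- function(theta) {
  if (inherits(theta, "an_field")) theta$theta else as.matrix(theta)
}
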