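#' Dimensionless control parameters of the active nematic model
#'
#' The model is controlled by three dimensionless numbers: the activity
#' number \eqn{A = L^2/\ell_c^2} (system size over active length, squared),
#' the viscosity ratio \eqn{R = \gamma/\eta} (rotational over shear
#' viscosity), and the sign of the active stress \eqn{S} (-1 contractile,
#' +1 extensile). Because the model has no flow alignment, the two signs of
#' \eqn{S} are related by a global rotation of the director by \eqn{\pi/2}
#' and are dynamically equivalent.
#'
#' Two time units are in use: the active time \eqn{\tau_a = \eta/|\zeta|},
#' in which the equations are derived, and the nematic relaxation time
#' \eqn{\tau_r = \gamma L^2 / K = A \tau_a}, in which results are reported
#' (it does not itself change with activity). \code{time_unit} selects the
#' unit in which flow fields, velocities and times are expressed by the
#' package's functions; internal integration always uses \eqn{\tau_r}.
#'
#' @param A Activity number, > 0. The sole bifurcation parameter.
#' @param R Viscosity ratio, > 0. Default 1.
#' @param S Sign of active stress, exactly -1 (contractile, default) or +1.
#' @param time_unit "tau_r" (default) or "tau_a".
#' @return An object of class \code{an_params}.
#' @seealso [physical_params()] to derive these from dimensional material
#'   constants.
#' @examples
#' p <- model_params(A = 500)
#' critical_activity(p)   # 10 * pi^2, the spontaneous-flow threshold
#' @export
model_params <- function(A, R = 1, S = -1, time_unit = c("tau_r", "tau_a")) {
  time_unit <- match.arg(time_unit)
  if (!is.numeric(A) || length(A) != 1 || !is.finite(A) || A <= 0) {
    stop("A must be a single positive number")
  }
  if (!is.numeric(R) || length(R) != 1 || !is.finite(R) || R <= 0) {
    stop("R must be a single positive number")
  }
  if (!S %in% c(-1, 1)) stop("S must be exactly -1 or +1")
  structure(list(A = as.numeric(A), R = as.numeric(R), S = as.numeric(S),
                 time_unit = time_unit),
            class = "an_params")
}

#' @export
print.an_params <- function(x, ...) {
  cat(sprintf("<an_params> A = %g, R = %g, S = %+d (%s), unit = %s\n",
              x$A, x$R, as.integer(x$S),
              if (x$S < 0) "contractile" else "extensile", x$time_unit))
  invisible(x)
}

#' Dimensional material parameters
#'
#' Convenience container for the dimensional constants of the model. The
#' dimensionless groups follow as \eqn{A = L^2 |\zeta| R / K},
#' \eqn{R = \gamma/\eta}, with active length
#' \eqn{\ell_c = \sqrt{K/(|\zeta| R)}}, active time \eqn{\tau_a = \eta/|\zeta|}
#' and relaxation time \eqn{\tau_r = \gamma L^2 / K}; the identity
#' \eqn{\tau_r = A \tau_a} holds by construction.
#'
#' @param eta Shear viscosity.
#' @param zeta Active stress coefficient (sign sets contractile/extensile).
#' @param K Frank elastic constant (one-constant approximation).
#' @param gamma Rotational viscosity.
#' @param L System size (default 1).
#' @return An object of class \code{an_physical} with the inputs plus the
#'   derived quantities \code{A}, \code{R}, \code{S}, \code{ell_c},
#'   \code{tau_a}, \code{tau_r}.
#' @export
physical_params <- function(eta, zeta, K, gamma, L = 1) {
  vals <- c(eta = eta, K = K, gamma = gamma, L = L)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("eta, K, gamma and L must be positive")
  }
  if (!is.finite(zeta) || zeta == 0) stop("zeta must be nonzero")
  R <- gamma / eta
  p <- list(eta = eta, zeta = zeta, K = K, gamma = gamma, L = L,
            R = R,
            S = sign(zeta),
            A = L^2 * abs(zeta) * R / K,
            ell_c = sqrt(K / (abs(zeta) * R)),
            tau_a = eta / abs(zeta),
            tau_r = gamma * L^2 / K)
  class(p) <- "an_physical"
  p
}

#' @rdname physical_params
#' @param x An \code{an_physical} object.
#' @param time_unit Passed on to [model_params()].
#' @export
as_model_params <- function(x, time_unit = c("tau_r", "tau_a")) {
  stopifnot(inherits(x, "an_physical"))
  model_params(A = x$A, R = x$R, S = x$S, time_unit = match.arg(time_unit))
}

# internal: velocity scale factor from tau_a units to the configured unit.
# v[L/tau_r] = A * v[L/tau_a]; frequencies/vorticity scale the same way.
unit_factor <- function(params) {
  if (params$time_unit == "tau_r") params$A else 1
}

# internal: warn when the grid cannot resolve the active length
# ell_c/L = A^(-1/2); we ask for at least two points per ell_c.
check_resolution_guard <- function(grid, params, check = TRUE) {
  if (isTRUE(check) && grid$n <= 2 * sqrt(params$A)) {
    warning(sprintf(
      "grid n = %d may under-resolve the active length at A = %g (need n > %.0f); pass check_resolution = FALSE to acknowledge",
      grid$n, params$A, 2 * sqrt(params$A)), call. = FALSE)
  }
  invisible(NULL)
}
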