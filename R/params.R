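#' Epileptor model parameters
#'
#' Constructs the parameter set of the six-variable Epileptor model (plus the
#' auxiliary low-pass filter state `u`). Defaults are the canonical values of
#' the model: `x0 = -1.6`, `y0 = 1`, `tau0 = 2857`, `tau2 = 10`, `tau1 = 1`,
#' `Irest1 = 3.1`, `Irest2 = 0.45`, `gamma = 0.01`, with the excitability
#' offset `m = 0` and the path-curvature sign `alpha = 1`.
#'
#' `x0` is the epileptogenicity: it places the z-nullcline relative to the
#' resting branch and so controls how prone the modelled region is to leave
#' the interictal state. `m` shifts the path followed by the fast subsystem
#' vertically in its parameter plane; `alpha` (+1 or -1 in practice) flips the
#' curvature of that path and gives access to the supercritical-Hopf-onset
#' bursting classes.
#'
#' @param x0 epileptogenicity (dimensionless).
#' @param y0 fast-subsystem input constant.
#' @param tau0 slow time constant (sets the z time scale).
#' @param tau1 fast time constant (the implicit unit time scale; recorded but
#'   not entering the equations, which are written in units of `tau1`).
#' @param tau2 intermediate time constant.
#' @param Irest1,Irest2 input currents of the fast and intermediate
#'   subsystems. `Irest2 = 0` silences the intermediate oscillator.
#' @param gamma decay rate of the low-pass filter `u` (1/time).
#' @param m excitability offset added to the path ordinate.
#' @param alpha sign/scale of the quadratic z-term in the path ordinate.
#' @return An object of class `epileptor_params` (a named list).
#' @seealso [epileptor_rhs()], [integrate_model()], [project_path()]
#' @examples
#' p <- epileptor_params(x0 = -2, Irest2 = 0)
#' @export
epileptor_params <- function(x0 = -1.6, y0 = 1, tau0 = 2857, tau1 = 1,
                             tau2 = 10, Irest1 = 3.1, Irest2 = 0.45,
                             gamma = 0.01, m = 0, alpha = 1) {
  p <- list(x0 = x0, y0 = y0, tau0 = tau0, tau1 = tau1, tau2 = tau2,
            Irest1 = Irest1, Irest2 = Irest2, gamma = gamma, m = m,
            alpha = alpha)
  stopifnot(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                     is.finite(v), logical(1)))
  if (!(tau0 > tau2 && tau2 > tau1 && tau1 > 0))
    stop("time-scale separation requires tau0 > tau2 > tau1 > 0")
  if (gamma <= 0) stop("gamma must be positive")
  structure(p, class = "epileptor_params")
}

#' Fast-subsystem parameters
#'
#' The Epileptor's fast (ictal-oscillation) subsystem written with all eight
#' coefficients explicit:
#' \deqn{\dot x = \nu y + a x^3 + b x^2 + \mu \; (x<0), \quad
#'       \dot x = \nu y + \bar m x + \mu \; (x \ge 0), \quad
#'       \dot y = y_0 + B x^2 + N y.}
#' The pair \eqn{(\mu, \bar m)} is slowly driven in the full model and spans
#' the bifurcation map; the remaining six coefficients default to the values
#' that recover the printed Epileptor equations
#' (`nu = 1`, `a = -1`, `b = 3`, `y0 = 1`, `B = -5`, `N = -1`).
#'
#' @param mu,mbar the two slowly driven parameters (map coordinates).
#' @param nu,a,b,y0,B,N fixed coefficients; `a`, `B` and `N` must be nonzero
#'   (the closed-form bifurcation curves divide by them).
#' @return An object of class `fast_params` (a named list).
#' @seealso [fixed_points()], [sn_curves()], [build_map()]
#' @examples
#' fp <- fast_params(mu = 0, mbar = 0)
#' @export
fast_params <- function(mu, mbar, nu = 1, a = -1, b = 3, y0 = 1, B = -5,
                        N = -1) {
  p <- list(nu = nu, a = a, b = b, mu = mu, mbar = mbar, y0 = y0, B = B,
            N = N)
  stopifnot(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                     is.finite(v), logical(1)))
  if (a == 0 || B == 0 || N == 0 || nu == 0)
    stop("degenerate coefficients: nu, a, B and N must be nonzero")
  structure(p, class = "fast_params")
}

#' DTB bursting model parameters
#'
#' Parameters of the minimal three-variable bursting model built on a layer
#' (fixed `mu2 > 0`) of the degenerate Takens-Bogdanov unfolding. The slowly
#' driven unfolding parameters move on the straight path
#' \eqn{\mu_1(z) = \mu_{1,0} + d_{\mu_1} z}, \eqn{\nu(z) = \nu_0 + d_\nu z},
#' and the slow variable obeys \eqn{\dot z = c (x - x_0)}.
#'
#' The default path is placed, with the layer at `mu2 = 0.07`, so that the
#' model performs SN/SH hysteresis-loop bursting: at rest (right branch of
#' fixed points, `x > x0`) `z` grows and pushes `mu1` across the fold; on the
#' limit cycle `z` shrinks and pulls the cycle into the saddle.
#'
#' @param mu2 fixed layer parameter (> 0).
#' @param mu1_0,nu_0 path start.
#' @param d_mu1,d_nu path direction.
#' @param c slow rate (0 < c << 1).
#' @param x0 excitability threshold for the slow variable.
#' @return An object of class `dtb_params` (a named list).
#' @seealso [dtb_rhs()], [dtb_path()]
#' @export
dtb_params <- function(mu2 = 0.07, mu1_0 = -0.006, nu_0 = 0.05,
                       d_mu1 = -0.002, d_nu = 0, c = 0.02, x0 = 0.1) {
  p <- list(mu2 = mu2, mu1_0 = mu1_0, nu_0 = nu_0, d_mu1 = d_mu1,
            d_nu = d_nu, c = c, x0 = x0)
  stopifnot(vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                     is.finite(v), logical(1)))
  if (!(c > 0 && c < 1)) stop("slow rate c must satisfy 0 < c << 1")
  if (mu2 <= 0) stop("layer condition requires mu2 > 0")
  structure(p, class = "dtb_params")
}

#' @export
print.epileptor_params <- function(x, ...) {
  cat("Epileptor parameters:\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.fast_params <- function(x, ...) {
  cat("Fast-subsystem parameters:\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.dtb_params <- function(x, ...) {
  cat("DTB bursting-model parameters:\n")
  print(unlist(x)); invisible(x)
}

#' Fast-subsystem parameters implied by full Epileptor parameters
#'
#' Maps Epileptor parameters and an instantaneous value of the slow drive
#' onto the explicit fast-parameter set: `nu = 1`, `a = -1`, `b = 3`,
#' `B = -5`, `N = -1`, `y0 = params$y0`, with `mu` and `mbar` as supplied
#' (typically from [project_path()]).
#'
#' @param params an [epileptor_params()] object.
#' @param mu,mbar map coordinates.
#' @return A [fast_params()] object.
#' @export
fast_params_from_epileptor <- function(params, mu, mbar) {
  stopifnot(inherits(params, "epileptor_params"))
  fast_params(mu = mu, mbar = mbar, nu = 1, a = -1, b = 3, y0 = params$y0,
              B = -5, N = -1)
}
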