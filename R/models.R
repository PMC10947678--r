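#' Epileptor right-hand side
#'
#' Time derivatives of the six-variable Epileptor. The state vector order is
#' fixed as `(x1, y1, z, x2, y2, u)` throughout the package. The `x1`
#' equation switches branch at `x1 = 0` and the `y2` equation at
#' `x2 = -0.25`; both branches agree at the switch, so the vector field is
#' continuous and no event handling is needed. For `x1 >= 0` the generalized
#' branch uses the path ordinate `mbar = 0.6*alpha*(z-4)^2 + m - x2`, which
#' reduces to the printed model when `alpha = 1`.
#'
#' The history integral driving the intermediate subsystem is carried as a
#' seventh equation, `du/dt = 0.002*x1 - gamma*u` with `u(t0) = 0`, which is
#' exact for the exponential kernel and avoids storing the past trajectory.
#'
#' @param state numeric vector `(x1, y1, z, x2, y2, u)` (names optional).
#' @param params an [epileptor_params()] object.
#' @return Numeric vector of the six time derivatives, in state order.
#' @examples
#' epileptor_rhs(rep(0, 6), epileptor_params())
#' @export
epileptor_rhs <- function(state, params) {
  stopifnot(inherits(params, "epileptor_params"), length(state) == 6)
  if (!all(is.finite(state)))
    stop("non-finite state: trajectory has diverged")
  x1 <- state[1]; y1 <- state[2]; z <- state[3]
  x2 <- state[4]; y2 <- state[5]; u <- state[6]
  p <- params

  dx1 <- if (x1 < 0) {
    y1 - x1^3 + 3 * x1^2 - z + p$Irest1
  } else {
    y1 + (p$m - x2 + 0.6 * p$alpha * (z - 4)^2) * x1 - z + p$Irest1
  }
  dy1 <- p$y0 - 5 * x1^2 - y1
  dz  <- (4 * (x1 - p$x0) - z) / p$tau0
  dx2 <- -y2 + x2 - x2^3 + p$Irest2 + u - 0.3 * (z - 3.5)
  dy2 <- if (x2 < -0.25) -y2 / p$tau2 else (-y2 + 6 * (x2 + 0.25)) / p$tau2
  du  <- 0.002 * x1 - p$gamma * u
  unname(c(dx1, dy1, dz, dx2, dy2, du))
}

#' Fast-subsystem right-hand side
#'
#' Derivatives of the isolated fast subsystem with explicit coefficients,
#' with the branch switch at `x = 0` (both branches equal `nu*y + mu` there).
#'
#' @param state numeric vector `(x, y)`.
#' @param fp a [fast_params()] object.
#' @return Numeric vector `(dx, dy)`.
#' @examples
#' fast_rhs(c(0, 0), fast_params(mu = -1, mbar = 0))
#' @export
fast_rhs <- function(state, fp) {
  stopifnot(inherits(fp, "fast_params"), length(state) == 2)
  if (!all(is.finite(state)))
    stop("non-finite state: trajectory has diverged")
  x <- state[1]; y <- state[2]
  dx <- if (x < 0) fp$nu * y + fp$a * x^3 + fp$b * x^2 + fp$mu
        else fp$nu * y + fp$mbar * x + fp$mu
  dy <- fp$y0 + fp$B * x^2 + fp$N * y
  unname(c(dx, dy))
}

#' DTB bursting-model right-hand side
#'
#' Derivatives of the three-variable DTB bursting model; the slowly driven
#' unfolding parameters are evaluated on the affine path
#' `mu1(z) = mu1_0 + d_mu1*z`, `nu(z) = nu_0 + d_nu*z`.
#'
#' @param state numeric vector `(x, y, z)`.
#' @param params a [dtb_params()] object.
#' @return Numeric vector `(dx, dy, dz)`.
#' @export
dtb_rhs <- function(state, params) {
  stopifnot(inherits(params, "dtb_params"), length(state) == 3)
  if (!all(is.finite(state)))
    stop("non-finite state: trajectory has diverged")
  x <- state[1]; y <- state[2]; z <- state[3]
  mu1 <- params$mu1_0 + params$d_mu1 * z
  nu  <- params$nu_0 + params$d_nu * z
  unname(c(-y,
           x^3 - params$mu2 * x - mu1 - y * (nu + x + x^2),
           params$c * (x - params$x0)))
}

#' Simulated field potential of an Epileptor trajectory
#'
#' The Epileptor's field-potential proxy is the combination of the fast and
#' intermediate variables, `x2 - x1`. For classes with a saddle-node bound
#' (onset or offset) it shows the characteristic DC (baseline) shift between
#' the interictal and ictal segments.
#'
#' @param traj a trajectory from [integrate_model()] with model `"epileptor"`.
#' @return Numeric vector, one value per sample.
#' @export
lfp <- function(traj) {
  stopifnot(inherits(traj, "dyn_trajectory"))
  if (!identical(attr(traj, "model"), "epileptor"))
    stop("lfp() is defined for full-Epileptor trajectories only")
  traj$x2 - traj$x1
}
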