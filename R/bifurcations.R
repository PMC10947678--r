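#' @keywords internal
#' Real roots of a cubic a3 x^3 + a2 x^2 + a1 x + a0, by the closed-form
#' depressed-cubic method (trigonometric in the three-real-root case,
#' Cardano otherwise). Complex roots are discarded at a tolerance on the
#' discriminant; near-double roots are returned as repeated real roots so
#' fold points are not lost to rounding.
solve_cubic_real <- function(a3, a2, a1, a0, tol = 1e-10) {
  if (a3 == 0) stop("degenerate cubic: leading coefficient is zero")
  # depressed form t^3 + p t + q with x = t - a2/(3 a3)
  sh <- a2 / (3 * a3)
  p <- a1 / a3 - sh^2 * 3
  q <- 2 * sh^3 - sh * a1 / a3 + a0 / a3
  disc <- -(4 * p^3 + 27 * q^2)
  if (abs(p) < tol && abs(q) < tol) {
    t <- c(0, 0, 0)
  } else if (disc > -tol && p < 0) {
    # three real roots (trigonometric form); clamp for |disc| ~ 0
    arg <- 3 * q / (2 * p) * sqrt(-3 / p)
    arg <- min(1, max(-1, arg))
    phi <- acos(arg)
    t <- 2 * sqrt(-p / 3) * cos((phi - 2 * pi * (0:2)) / 3)
  } else {
    # one real root (Cardano)
    s <- sqrt(q^2 / 4 + p^3 / 27)
    cb <- function(v) sign(v) * abs(v)^(1 / 3)
    t <- cb(-q / 2 + s) + cb(-q / 2 - s)
  }
  sort(t - sh)
}

#' Jacobian of the fast subsystem at a point
#'
#' The Jacobian of the piecewise fast vector field,
#' `[[3*a*x^2 + 2*b*x (x<0) or mbar (x>=0), nu], [2*B*x, N]]`.
#' At the seam `x = 0` the two one-sided limits differ (`0` vs `mbar` in the
#' top-left entry); the `x >= 0` branch is returned there, matching the
#' branch convention of the vector field.
#'
#' @param fp a [fast_params()] object.
#' @param x x-coordinate at which to evaluate.
#' @return A 2x2 numeric matrix.
#' @export
jacobian_fast <- function(fp, x) {
  stopifnot(inherits(fp, "fast_params"), is.finite(x))
  j11 <- if (x < 0) 3 * fp$a * x^2 + 2 * fp$b * x else fp$mbar
  matrix(c(j11, 2 * fp$B * x, fp$nu, fp$N), 2, 2)
}

stability_label <- function(tr, dt, tol = 1e-9) {
  if (abs(dt) < tol || abs(tr) < tol && dt > 0) return("non-hyperbolic")
  if (dt < 0) return("saddle")
  node <- tr^2 >= 4 * dt
  if (tr < 0) if (node) "stable-node" else "stable-focus"
  else if (node) "unstable-node" else "unstable-focus"
}

#' Fixed points of the fast subsystem
#'
#' Solves the fixed-point conditions of the piecewise fast subsystem: the
#' cubic `a*x^3 + (b - nu*B/N)*x^2 + (mu - nu*y0/N) = 0` restricted to
#' `x < 0` and the quadratic `-(nu*B/N)*x^2 + mbar*x + (mu - nu*y0/N) = 0`
#' restricted to `x >= 0`, each with `y = -(y0 + B*x^2)/N`. The cubic is
#' solved in closed form (trigonometric method) rather than iteratively, so
#' roots remain reliable arbitrarily close to the folds.
#'
#' Stability is classified from the trace and determinant of
#' [jacobian_fast()]. A root at the seam `x = 0` is labelled branch
#' `"boundary"` and stability `"non-hyperbolic"`: the Jacobian limits from
#' the two sides disagree there, so no hyperbolic label is justified.
#'
#' @param fp a [fast_params()] object.
#' @param tol roots with `|x| < tol` are treated as seam roots; duplicated
#'   seam roots from the two branches are merged.
#' @return A data frame with one row per fixed point, sorted by `x`, with
#'   columns `x`, `y`, `branch` (`"negative"`, `"boundary"`, `"positive"`),
#'   `stability`, `trace`, `det`.
#' @examples
#' fixed_points(fast_params(mu = 0, mbar = 0))
#' @export
fixed_points <- function(fp, tol = 1e-9) {
  stopifnot(inherits(fp, "fast_params"))
  c2 <- fp$b - fp$nu * fp$B / fp$N
  c0 <- fp$mu - fp$nu * fp$y0 / fp$N
  qa <- -fp$nu * fp$B / fp$N
  if (qa == 0) stop("degenerate quadratic branch: nu*B/N is zero")

  roots_neg <- solve_cubic_real(fp$a, c2, 0, c0)
  roots_neg <- roots_neg[roots_neg < tol]

  disc <- fp$mbar^2 - 4 * qa * c0
  roots_pos <- if (disc >= 0) (-fp$mbar + c(-1, 1) * sqrt(disc)) / (2 * qa)
               else numeric(0)
  roots_pos <- roots_pos[roots_pos > -tol]

  xs <- c(roots_neg, roots_pos)
  seam <- abs(xs) < tol
  xs[seam] <- 0
  xs <- xs[!duplicated(round(xs / tol))]  # merge seam duplicates
  xs <- sort(xs)
  if (length(xs) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      branch = character(0), stability = character(0),
                      trace = numeric(0), det = numeric(0)))

  y <- -(fp$y0 + fp$B * xs^2) / fp$N
  branch <- ifelse(xs == 0, "boundary", ifelse(xs < 0, "negative", "positive"))
  tr <- dt <- numeric(length(xs))
  stab <- character(length(xs))
  for (i in seq_along(xs)) {
    J <- jacobian_fast(fp, xs[i])
    tr[i] <- J[1, 1] + J[2, 2]
    dt[i] <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    stab[i] <- if (branch[i] == "boundary") "non-hyperbolic"
               else stability_label(tr[i], dt[i])
  }
  data.frame(x = xs, y = y, branch = branch, stability = stab,
             trace = tr, det = dt)
}

#' Closed-form saddle-node curves of the fast subsystem
#'
#' The two-parameter plane \eqn{(\mu, \bar m)} contains three fold-type
#' curves delimiting the three-fixed-point wedge:
#' \describe{
#'   \item{SN-}{`mu = nu*y0/N - (4/(27*a^2))*(b - nu*B/N)^3`, a vertical
#'     line: fold of the two negative-branch fixed points at
#'     `x = -2*(b - nu*B/N)/(3*a)`.}
#'   \item{SN+}{`mu(mbar) = nu*y0/N - N*mbar^2/(4*B*nu)`, a parabola: fold
#'     of the two positive-branch fixed points at `x = mbar*N/(2*nu*B)`,
#'     valid where that fold abscissa is nonnegative (`mbar >= 0` with
#'     default signs).}
#'   \item{SN0}{`mu = nu*y0/N` for `mbar <= 0`: the positive and negative
#'     branches merge through the seam `x = 0`. Because the Jacobian limits
#'     disagree at the seam this is a pseudo-fold, not a genuine saddle-node,
#'     but it bounds the wedge and acts as a fold for bursting; it is
#'     labelled distinctly in all outputs.}
#' }
#'
#' @param fp a [fast_params()] object (`mu`, `mbar` ignored).
#' @return A list of class `sn_curves` with elements `sn_minus`
#'   (`mu`, `x_fold`), `sn_plus` (`mu_of_mbar` closure, `x_fold_of_mbar`
#'   closure, `mbar_valid` predicate), and `sn_zero` (`mu`, `mbar_max = 0`).
#' @examples
#' sn_curves(fast_params(mu = 0, mbar = 0))$sn_minus$mu  # 5/27 with defaults
#' @export
sn_curves <- function(fp) {
  stopifnot(inherits(fp, "fast_params"))
  muy <- fp$nu * fp$y0 / fp$N
  c2 <- fp$b - fp$nu * fp$B / fp$N
  sn_minus <- list(mu = muy - 4 / (27 * fp$a^2) * c2^3,
                   x_fold = -2 * c2 / (3 * fp$a))
  mu_of_mbar <- function(mbar) muy - fp$N * mbar^2 / (4 * fp$B * fp$nu)
  x_fold_of_mbar <- function(mbar) mbar * fp$N / (2 * fp$nu * fp$B)
  sn_plus <- list(mu_of_mbar = mu_of_mbar, x_fold_of_mbar = x_fold_of_mbar,
                  mbar_valid = function(mbar) x_fold_of_mbar(mbar) >= 0)
  structure(list(sn_minus = sn_minus, sn_plus = sn_plus,
                 sn_zero = list(mu = muy, mbar_max = 0)),
            class = "sn_curves")
}

#' Andronov-Hopf line of the fast subsystem
#'
#' Trace-zero candidates of the Jacobian are the roots of
#' `3*a*x^2 + 2*b*x + N = 0` on the `x < 0` branch and the line
#' `mbar = -N` on the `x >= 0` branch. With the default coefficients both
#' negative-branch candidates are nonnegative, so they never meet the
#' fixed-point condition and the only Hopf curve is the horizontal line
#' `mbar = -N`, valid where the upper-branch fixed point exists with
#' positive determinant (i.e. `x > mbar*N/(2*nu*B)`, which holds for
#' `mu` greater than the Takens-Bogdanov value).
#'
#' @param fp a [fast_params()] object (`mu`, `mbar` ignored).
#' @return A list of class `hopf_curve` with `mbar` (the line), `mu_min`
#'   (validity threshold, the TB `mu`), `valid(mu)` predicate,
#'   `neg_branch_candidates` (trace-zero abscissae for `x < 0`, possibly
#'   empty) and `has_negative_branch_hopf` (logical).
#' @examples
#' hopf_curve(fast_params(mu = 0, mbar = 0))$mbar  # 1 with defaults
#' @export
hopf_curve <- function(fp) {
  stopifnot(inherits(fp, "fast_params"))
  mbar_h <- -fp$N
  tb <- tb_point(fp)
  disc <- 4 * fp$b^2 - 12 * fp$a * fp$N
  cand <- if (disc >= 0) (-2 * fp$b + c(-1, 1) * sqrt(disc)) / (6 * fp$a)
          else numeric(0)
  structure(list(
    mbar = mbar_h,
    mu_min = tb[["mu"]],
    valid = function(mu) mu > tb[["mu"]],
    neg_branch_candidates = cand,
    has_negative_branch_hopf = any(cand < 0)
  ), class = "hopf_curve")
}

#' Takens-Bogdanov point of the fast subsystem
#'
#' The codimension-2 point where the Hopf line `mbar = -N` meets the SN+
#' parabola: `x = mbar*N/(2*nu*B)` with `mu` from the SN+ formula. Both the
#' trace and the determinant of the Jacobian vanish there.
#'
#' @param fp a [fast_params()] object (`mu`, `mbar` ignored).
#' @return Named numeric vector `(mu, mbar, x)`.
#' @examples
#' tb_point(fast_params(mu = 0, mbar = 0))  # (-1.05, 1, 0.1) with defaults
#' @export
tb_point <- function(fp) {
  stopifnot(inherits(fp, "fast_params"))
  mbar <- -fp$N
  x <- mbar * fp$N / (2 * fp$nu * fp$B)
  mu <- fp$nu * fp$y0 / fp$N - fp$N * mbar^2 / (4 * fp$B * fp$nu)
  c(mu = mu, mbar = mbar, x = x)
}

#' Fixed-point census at a map location
#'
#' Counts fixed points and stable fixed points of the fast subsystem at the
#' `(mu, mbar)` carried by `fp`. The limit-cycle flag is left `NA`: limit
#' cycles are global objects and are detected by simulation in
#' [classify_region()]. Points within `on_tol` of an analytic bifurcation
#' curve are tagged `on_curve` and not assigned a configuration.
#'
#' @param fp a [fast_params()] object.
#' @param on_tol curve-proximity tolerance for the `on_curve` tag.
#' @return A list with `n_fp`, `n_stable_fp`, `has_stable_lc` (`NA`),
#'   `on_curve`, and the `fixed_points` data frame.
#' @export
local_region_config <- function(fp, on_tol = 1e-8) {
  stopifnot(inherits(fp, "fast_params"))
  pts <- fixed_points(fp)
  sn <- sn_curves(fp)
  hp <- hopf_curve(fp)
  d <- abs(fp$mu - sn$sn_minus$mu)
  if (sn$sn_plus$mbar_valid(fp$mbar))
    d <- c(d, abs(fp$mu - sn$sn_plus$mu_of_mbar(fp$mbar)))
  if (fp$mbar <= sn$sn_zero$mbar_max)
    d <- c(d, abs(fp$mu - sn$sn_zero$mu))
  if (hp$valid(fp$mu))
    d <- c(d, abs(fp$mbar - hp$mbar))
  list(n_fp = nrow(pts),
       n_stable_fp = sum(grepl("^stable", pts$stability)),
       has_stable_lc = NA,
       on_curve = any(d < on_tol),
       fixed_points = pts)
}

#' Assemble the analytic bifurcation set
#'
#' Bundles the closed-form curves ([sn_curves()], [hopf_curve()],
#' [tb_point()]) of a fast-parameter family into one object; the
#' saddle-homoclinic polyline is global and must be inferred from a
#' simulated map ([infer_sh_curve()]), after which it can be attached via
#' the `sh` field.
#'
#' @param fp a [fast_params()] object (`mu`, `mbar` ignored).
#' @param sh optional saddle-homoclinic polyline (data frame `mbar`, `mu`).
#' @return An object of class `bifurcation_set`.
#' @export
bifurcation_set <- function(fp, sh = NULL) {
  structure(list(params = fp, sn = sn_curves(fp), hopf = hopf_curve(fp),
                 tb = tb_point(fp), sh = sh),
            class = "bifurcation_set")
}

#' @export
print.bifurcation_set <- function(x, ...) {
  cat("Fast-subsystem bifurcation set\n")
  cat(sprintf("  SN-  : mu = %.6f (fold x = %.4f)\n",
              x$sn$sn_minus$mu, x$sn$sn_minus$x_fold))
  cat(sprintf("  SN+  : mu(mbar) = %.6f - parabola; at mbar = -N: %.6f\n",
              x$sn$sn_zero$mu, x$sn$sn_plus$mu_of_mbar(-x$params$N)))
  cat(sprintf("  SN0  : mu = %.6f (mbar <= 0; pseudo-fold at the seam)\n",
              x$sn$sn_zero$mu))
  cat(sprintf("  Hopf : mbar = %.6f (valid mu > %.6f)\n",
              x$hopf$mbar, x$hopf$mu_min))
  cat(sprintf("  TB   : (mu, mbar, x) = (%.6f, %.6f, %.6f)\n",
              x$tb[["mu"]], x$tb[["mbar"]], x$tb[["x"]]))
  cat(if (is.null(x$sh)) "  SH   : not inferred (see infer_sh_curve)\n"
      else sprintf("  SH   : polyline with %d vertices\n", nrow(x$sh)))
  invisible(x)
}
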