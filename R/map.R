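#' Map simulation protocol
#'
#' The protocol used to probe each map cell: integrate the fast subsystem
#' from the upper (largest-x) fixed point offset by `epsilon` in x, discard
#' the transient, and measure the amplitude and dominant frequency of the
#' remaining `x` samples. Defaults follow the Epileptor protocol (600 time
#' units, first 300 discarded, `epsilon = 0.05`); [dtb_map_protocol()] gives
#' the longer, smaller-offset variant used for the DTB layer, whose
#' dynamics are two orders of magnitude slower in amplitude.
#'
#' @param t_total total simulated time (time units, read as seconds so
#'   frequencies are reported in Hz).
#' @param t_discard initial transient removed before measuring.
#' @param epsilon initial x-offset from the probing fixed point.
#' @param sample_dt uniform resampling step for spectra.
#' @param amp_threshold amplitudes below this (in x-units) count as
#'   convergence to a fixed point; two orders of magnitude below typical
#'   limit-cycle amplitudes.
#' @return An object of class `map_protocol`.
#' @export
map_protocol <- function(t_total = 600, t_discard = 300, epsilon = 0.05,
                         sample_dt = 0.1, amp_threshold = 1e-3) {
  stopifnot(t_discard > 0, t_discard < t_total, epsilon > 0)
  structure(list(t_total = t_total, t_discard = t_discard,
                 epsilon = epsilon, sample_dt = sample_dt,
                 amp_threshold = amp_threshold),
            class = "map_protocol")
}

#' @rdname map_protocol
#' @export
dtb_map_protocol <- function(t_total = 2000, t_discard = 500,
                             epsilon = 5e-4, sample_dt = 0.1,
                             amp_threshold = 1e-4) {
  map_protocol(t_total, t_discard, epsilon, sample_dt, amp_threshold)
}

#' Dominant frequency by Hann-windowed DFT
#'
#' Applies a Hann window, takes the DFT, and returns the frequency of the
#' largest nonzero bin, refined by quadratic interpolation of the three
#' log-magnitude bins around the maximum. Resolution before interpolation
#' is `1/(n*dt)`.
#'
#' @param x numeric series, uniformly sampled.
#' @param dt sampling step (seconds).
#' @return Frequency in Hz (0 for a constant series).
#' @export
dominant_frequency <- function(x, dt) {
  n <- length(x)
  if (n < 8 || max(x) - min(x) == 0) return(0)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # Hann window
  spec <- Mod(stats::fft((x - mean(x)) * w))[seq_len(n %/% 2)]
  spec[1] <- 0  # exclude the zero bin
  k <- which.max(spec)
  if (spec[k] == 0) return(0)
  # quadratic interpolation of the peak (log magnitude)
  delta <- 0
  if (k > 1 && k < length(spec) && spec[k - 1] > 0 && spec[k + 1] > 0) {
    lm <- log(spec[(k - 1):(k + 1)])
    den <- lm[1] - 2 * lm[2] + lm[3]
    if (den < 0) delta <- 0.5 * (lm[1] - lm[3]) / den
  }
  (k - 1 + delta) / (n * dt)
}

upper_probe_point <- function(fp, epsilon) {
  pts <- fixed_points(fp)
  if (nrow(pts) == 0) stop("no fixed point to probe at this map location")
  i <- which.max(pts$x)  # "upper" = largest x; unique point if only one
  c(pts$x[i] + epsilon, pts$y[i])
}

dtb_fast_fixed_points <- function(mu2, mu1, nu) {
  xs <- solve_cubic_real(1, 0, -mu2, -mu1)
  tr <- -(nu + xs + xs^2)
  dt <- 3 * xs^2 - mu2
  stab <- vapply(seq_along(xs),
                 function(i) stability_label(tr[i], dt[i]), "")
  data.frame(x = xs, y = 0, branch = ifelse(xs < 0, "negative", "positive"),
             stability = stab, trace = tr, det = dt)
}

#' Limit-cycle amplitude and frequency at one map location
#'
#' Runs the map protocol at a single `(mu, mbar)` cell (or `(mu1, nu)` cell
#' of the DTB layer): integrate from the upper fixed point plus `epsilon`,
#' drop the transient, and measure `amplitude = max(x) - min(x)` and the
#' dominant Hann/DFT frequency of `x`. A cell whose post-transient
#' amplitude falls below `protocol$amp_threshold` is flagged
#' `converged_to_fp` (frequency 0).
#'
#' @param fp a [fast_params()] object, or for `model = "dtb_fast"` a list
#'   `(mu2, mu1, nu)`.
#' @param protocol a [map_protocol()] object.
#' @param model `"fast"` (Epileptor fast subsystem) or `"dtb_fast"`.
#' @param opts solver options.
#' @return List `(amplitude, frequency, converged_to_fp, failed)`.
#' @export
limit_cycle_stats <- function(fp, protocol = map_protocol(),
                              model = c("fast", "dtb_fast"),
                              opts = solve_options()) {
  model <- match.arg(model)
  probe <- if (model == "fast") {
    upper_probe_point(fp, protocol$epsilon)
  } else {
    pts <- dtb_fast_fixed_points(fp$mu2, fp$mu1, fp$nu)
    # the non-resting fixed point: rest is the rightmost; probe the
    # leftmost (active) point when several exist
    i <- if (nrow(pts) > 1) which.min(pts$x) else 1
    c(pts$x[i] + protocol$epsilon, pts$y[i])
  }
  traj <- tryCatch(
    integrate_model(model, fp, probe, c(0, protocol$t_total),
                    solve_options(max_step = opts$max_step,
                                  rel_tol = opts$rel_tol,
                                  abs_tol = opts$abs_tol,
                                  sample_dt = protocol$sample_dt,
                                  method = opts$method)),
    error = function(e) NULL)
  if (is.null(traj))
    return(list(amplitude = NA_real_, frequency = NA_real_,
                converged_to_fp = NA, failed = TRUE))
  x <- traj$x[traj$time >= protocol$t_discard]
  amp <- max(x) - min(x)
  conv <- amp < protocol$amp_threshold
  freq <- if (conv) 0 else dominant_frequency(x, protocol$sample_dt)
  list(amplitude = amp, frequency = freq, converged_to_fp = conv,
       failed = FALSE)
}

#' Build an amplitude/frequency map over the slow-parameter plane
#'
#' Applies [limit_cycle_stats()] to every cell of a rectangular
#' `(mu, mbar)` grid (or `(mu1, nu)` grid for the DTB layer) and, for the
#' Epileptor fast subsystem, attaches the analytic fixed-point census of
#' each cell. The result is deterministic: no noise enters the protocol.
#'
#' @param fp_base a [fast_params()] object supplying the fixed coefficients
#'   (`mu`, `mbar` are overwritten per cell); for `model = "dtb_fast"` a
#'   list with `mu2`.
#' @param mu_range,mbar_range numeric length-2 ranges (for the DTB layer
#'   these are the `mu1` and `nu` ranges).
#' @param resolution number of cells per axis (length 1 or 2).
#' @param protocol a [map_protocol()] object.
#' @param model `"fast"` or `"dtb_fast"`.
#' @param opts solver options.
#' @return An object of class `map_grid`: list with `mu_values`,
#'   `mbar_values`, matrices `amplitude`, `frequency`, `converged_to_fp`,
#'   `n_fp`, `n_stable_fp` (rows index `mu`, columns `mbar`), the protocol
#'   and the model tag.
#' @export
build_map <- function(fp_base, mu_range, mbar_range, resolution = 20,
                      protocol = map_protocol(),
                      model = c("fast", "dtb_fast"),
                      opts = solve_options()) {
  model <- match.arg(model)
  stopifnot(diff(mu_range) > 0, diff(mbar_range) > 0)
  resolution <- rep(resolution, length.out = 2)
  mu_values <- seq(mu_range[1], mu_range[2], length.out = resolution[1])
  mbar_values <- seq(mbar_range[1], mbar_range[2],
                     length.out = resolution[2])
  dims <- c(length(mu_values), length(mbar_values))
  amp <- freq <- matrix(NA_real_, dims[1], dims[2])
  conv <- matrix(NA, dims[1], dims[2])
  nfp <- nsfp <- matrix(NA_integer_, dims[1], dims[2])
  for (j in seq_along(mbar_values)) {
    for (i in seq_along(mu_values)) {
      cellp <- if (model == "fast") {
        fast_params(mu = mu_values[i], mbar = mbar_values[j],
                    nu = fp_base$nu, a = fp_base$a, b = fp_base$b,
                    y0 = fp_base$y0, B = fp_base$B, N = fp_base$N)
      } else {
        list(mu2 = fp_base$mu2, mu1 = mu_values[i], nu = mbar_values[j])
      }
      st <- limit_cycle_stats(cellp, protocol, model = model, opts = opts)
      amp[i, j] <- st$amplitude
      freq[i, j] <- st$frequency
      conv[i, j] <- st$converged_to_fp
      pts <- if (model == "fast") fixed_points(cellp)
             else dtb_fast_fixed_points(cellp$mu2, cellp$mu1, cellp$nu)
      nfp[i, j] <- nrow(pts)
      nsfp[i, j] <- sum(grepl("^stable", pts$stability))
    }
  }
  structure(list(mu_values = mu_values, mbar_values = mbar_values,
                 amplitude = amp, frequency = freq, converged_to_fp = conv,
                 n_fp = nfp, n_stable_fp = nsfp, protocol = protocol,
                 model = model),
            class = "map_grid")
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("map_grid (%s): %d x %d cells, mu in [%g, %g], %s in [%g, %g]\n",
              x$model, length(x$mu_values), length(x$mbar_values),
              min(x$mu_values), max(x$mu_values),
              if (x$model == "fast") "mbar" else "nu",
              min(x$mbar_values), max(x$mbar_values)))
  osc <- sum(!x$converged_to_fp, na.rm = TRUE)
  cat(sprintf("  oscillatory cells: %d / %d\n", osc, length(x$amplitude)))
  invisible(x)
}

#' Infer the saddle-homoclinic curve from the frequency map
#'
#' The saddle-homoclinic bifurcation is global, so it is located from the
#' simulated map rather than analytically: the limit-cycle frequency scales
#' to zero on approach, so for each `mbar` row inside the oscillatory band
#' (above the Hopf line for the default coefficients) the SH boundary is
#' the left edge of the oscillatory cells, linearly interpolated in `mu`
#' between the last oscillatory cell and its non-oscillatory neighbour
#' using the frequency trend. Theory predicts the polyline stems from the
#' Takens-Bogdanov point and reaches the opposite saddle-node curve.
#'
#' @param grid a `map_grid` from [build_map()] (Epileptor fast model).
#' @param freq_floor frequencies below this count as "scaled to zero";
#'   default twice the spectral resolution of the protocol.
#' @return Data frame `mbar`, `mu` (one vertex per oscillatory row; empty
#'   with a warning if the grid has no oscillatory cells).
#' @export
infer_sh_curve <- function(grid, freq_floor = NULL) {
  stopifnot(inherits(grid, "map_grid"))
  if (is.null(freq_floor))
    freq_floor <- 2 / (grid$protocol$t_total - grid$protocol$t_discard)
  osc <- !grid$converged_to_fp & grid$frequency > freq_floor
  osc[is.na(osc)] <- FALSE
  rows <- which(apply(osc, 2, any))
  if (length(rows) == 0) {
    warning("no oscillatory cells in the grid; empty SH polyline")
    return(data.frame(mbar = numeric(0), mu = numeric(0)))
  }
  verts <- lapply(rows, function(j) {
    i1 <- which(osc[, j])[1]  # leftmost oscillatory cell
    mu1 <- grid$mu_values[i1]
    if (i1 == 1) return(data.frame(mbar = grid$mbar_values[j], mu = mu1))
    # extrapolate the frequency trend to zero between cells i1-1 and i1
    f1 <- grid$frequency[i1, j]
    f2 <- if (i1 + 1 <= length(grid$mu_values) && osc[i1 + 1, j])
      grid$frequency[i1 + 1, j] else NA_real_
    mu0 <- grid$mu_values[i1 - 1]
    mu_b <- if (is.finite(f2) && f2 > f1) {
      # linear frequency-vs-mu extrapolation to f = 0, clipped to the cell
      max(mu0, mu1 - f1 * (grid$mu_values[i1 + 1] - mu1) / (f2 - f1))
    } else {
      (mu0 + mu1) / 2
    }
    data.frame(mbar = grid$mbar_values[j], mu = mu_b)
  })
  do.call(rbind, verts)
}

#' Attractor configuration at one map location
#'
#' Combines the analytic fixed-point census with simulated limit-cycle
#' detection (the map protocol probes near the upper fixed point; a second
#' probe is started near the resting point when one exists, confirming its
#' stability). The `(n_stable_fp, n_fp, has_stable_lc)` tuple identifies
#' the qualitative state-space configuration; over the mapped rectangle
#' exactly five distinct tuples occur.
#'
#' @param fp a [fast_params()] object.
#' @param protocol a [map_protocol()] object.
#' @param opts solver options.
#' @return A list `(n_stable_fp, n_fp, has_stable_lc, on_curve, unknown)`.
#' @export
classify_region <- function(fp, protocol = map_protocol(),
                            opts = solve_options()) {
  cfg <- local_region_config(fp)
  st <- limit_cycle_stats(fp, protocol, model = "fast", opts = opts)
  if (st$failed)
    return(list(n_stable_fp = cfg$n_stable_fp, n_fp = cfg$n_fp,
                has_stable_lc = NA, on_curve = cfg$on_curve,
                unknown = TRUE))
  list(n_stable_fp = cfg$n_stable_fp, n_fp = cfg$n_fp,
       has_stable_lc = !st$converged_to_fp, on_curve = cfg$on_curve,
       unknown = FALSE)
}

#' Census of attractor configurations over a map grid
#'
#' Tabulates the distinct `(n_stable_fp, n_fp, has_stable_lc)` tuples of a
#' simulated [build_map()] grid.
#'
#' @param grid a `map_grid`.
#' @return Data frame of distinct configurations with cell counts, ordered
#'   by frequency.
#' @export
region_census <- function(grid) {
  stopifnot(inherits(grid, "map_grid"))
  key <- sprintf("(%d,%d,%s)", grid$n_stable_fp, grid$n_fp,
                 ifelse(grid$converged_to_fp, "noLC", "LC"))
  tab <- sort(table(key), decreasing = TRUE)
  out <- data.frame(config = names(tab), cells = as.integer(tab),
                    row.names = NULL)
  parts <- regmatches(out$config,
                      regexec("\\((\\d+),(\\d+),(\\w+)\\)", out$config))
  out$n_stable_fp <- as.integer(vapply(parts, `[`, "", 2))
  out$n_fp <- as.integer(vapply(parts, `[`, "", 3))
  out$has_stable_lc <- vapply(parts, `[`, "", 4) == "LC"
  out
}
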