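#' Project a full-Epileptor trajectory onto the fast-parameter map
#'
#' The instantaneous location of the fast subsystem in its parameter plane
#' is the algebraic image of the slower variables:
#' `mu = Irest1 - z` and `mbar = 0.6*alpha*(z-4)^2 + m - x2` (raw `x2`, no
#' smoothing). Intermediate-subsystem oscillations therefore appear as
#' fast excursions ("spikes") in the `mbar` component of the path.
#'
#' @param traj a full-Epileptor `dyn_trajectory`.
#' @param params the [epileptor_params()] used for the run (defaults to the
#'   parameters carried by the trajectory).
#' @return Data frame `t`, `mu`, `mbar`, one row per sample.
#' @export
project_path <- function(traj, params = attr(traj, "params")) {
  stopifnot(inherits(traj, "dyn_trajectory"),
            identical(attr(traj, "model"), "epileptor"),
            inherits(params, "epileptor_params"))
  data.frame(t = traj$time,
             mu = params$Irest1 - traj$z,
             mbar = 0.6 * params$alpha * (traj$z - 4)^2 + params$m - traj$x2)
}

#' Project a DTB trajectory onto its unfolding-parameter path
#'
#' The affine image `(mu1(z), nu(z))` of the slow variable; by construction
#' it lies exactly on the straight path line of the model.
#'
#' @param params a [dtb_params()] object (defaults to the trajectory's).
#' @param traj a DTB `dyn_trajectory`.
#' @return Data frame `t`, `mu1`, `nu`.
#' @export
dtb_path <- function(params, traj) {
  if (missing(params) || is.null(params)) params <- attr(traj, "params")
  stopifnot(inherits(traj, "dyn_trajectory"),
            identical(attr(traj, "model"), "dtb"),
            inherits(params, "dtb_params"))
  data.frame(t = traj$time,
             mu1 = params$mu1_0 + params$d_mu1 * traj$z,
             nu = params$nu_0 + params$d_nu * traj$z)
}

# Block-decimated sliding envelope of a uniformly sampled series.
# Exact max/min over centered windows of `window` time units, computed on
# 1-time-unit blocks for speed; returns block-center times, envelope
# amplitude, and envelope midline.
amplitude_envelope <- function(t, x, window = 50) {
  dt <- t[2] - t[1]
  stride <- max(1L, round(1 / dt))     # one block per time unit
  nblock <- length(x) %/% stride
  xm <- matrix(x[seq_len(nblock * stride)], nrow = stride)
  bmax <- apply(xm, 2, max)
  bmin <- apply(xm, 2, min)
  bt <- t[seq(1, nblock * stride, by = stride)] + (stride - 1) * dt / 2
  w <- max(3L, round(window / (stride * dt)))
  if (w %% 2 == 0) w <- w + 1L
  rmax <- zoo::rollmax(zoo::zoo(bmax), w, fill = NA, align = "center")
  rmin <- -zoo::rollmax(zoo::zoo(-bmin), w, fill = NA, align = "center")
  keep <- !is.na(rmax)
  data.frame(t = bt[keep], amp = as.numeric(rmax - rmin)[keep],
             mid = as.numeric((rmax + rmin) / 2)[keep])
}

# Block medians of a uniformly sampled series on `block`-time-unit blocks.
block_median <- function(t, x, block = 1) {
  dt <- t[2] - t[1]
  stride <- max(1L, round(block / dt))
  nblock <- length(x) %/% stride
  xm <- matrix(x[seq_len(nblock * stride)], nrow = stride)
  list(t = t[seq(1, nblock * stride, by = stride)] + (stride - 1) * dt / 2,
       v = apply(xm, 2, stats::median))
}

# Middle-branch (separatrix) abscissa of the negative fixed-point branch at
# scalar mu; NA where the wedge is absent.
middle_branch_x <- function(fp_base, mu) {
  vapply(mu, function(m) {
    p <- fast_params(mu = m, mbar = 0, nu = fp_base$nu, a = fp_base$a,
                     b = fp_base$b, y0 = fp_base$y0, B = fp_base$B,
                     N = fp_base$N)
    neg <- fixed_points(p)
    neg <- neg$x[neg$branch == "negative"]
    if (length(neg) >= 2) max(neg) else NA_real_
  }, numeric(1))
}

#' Detect seizure onset/offset events of a burster trajectory
#'
#' Builds a sliding-window amplitude envelope of `x1` (or `x` for the DTB
#' model) and marks an onset when the envelope crosses `amp_on` upward and
#' an offset when it crosses `amp_off` downward, with hysteresis
#' (`amp_on > amp_off`). For non-oscillating bursters (SN/SN alternation)
#' no envelope event exists; events are then the switches of the envelope
#' midline across the unstable middle-branch abscissa at the instantaneous
#' path `mu` (attribute `mode = "branch"`).
#'
#' @param traj a `dyn_trajectory` of the Epileptor or DTB model.
#' @param envelope_window envelope window (time units); much longer than a
#'   fast period, much shorter than a burst.
#' @param amp_on,amp_off envelope thresholds in x-units.
#' @return Data frame `kind` (`"onset"`/`"offset"`), `t`, `mu`, `mbar`
#'   (path location; `mu1`, `nu` for DTB), with attribute `mode`; empty if
#'   no events found.
#' @export
detect_transitions <- function(traj, envelope_window = 50, amp_on = 0.5,
                               amp_off = 0.2) {
  stopifnot(inherits(traj, "dyn_trajectory"), amp_on > amp_off)
  model <- attr(traj, "model")
  stopifnot(model %in% c("epileptor", "dtb"))
  xname <- if (model == "epileptor") "x1" else "x"
  env <- amplitude_envelope(traj$time, traj[[xname]], envelope_window)

  events <- envelope_events(env, amp_on, amp_off)
  mode <- "envelope"
  # A branch jump excites the envelope for about one window length even
  # without sustained oscillation (the jump itself spans the window).
  # Episodes shorter than a few windows are therefore jump transients,
  # not oscillation, and are dropped; if nothing longer remains there is
  # no sustained oscillation at all and detection falls back to
  # branch-switch events.
  if (nrow(events) > 0) {
    eps <- burst_pairs(events, drop_first = FALSE)
    durs <- vapply(eps, function(p) p$offset$t - p$onset$t, 0)
    if (length(durs) > 0) {
      keep <- durs >= 2.5 * envelope_window
      if (!any(keep)) {
        events <- events[0, ]
      } else if (!all(keep)) {
        kept <- eps[keep]
        events <- do.call(rbind, lapply(kept, function(p)
          rbind(p$onset, p$offset)))
      }
    }
  }
  if (nrow(events) == 0 && model == "epileptor") {
    params <- attr(traj, "params")
    fpb <- fast_params_from_epileptor(params, 0, 0)
    mu_env <- stats::approx(traj$time, params$Irest1 - traj$z, env$t)$y
    xmid <- middle_branch_x(fpb, mu_env)
    xmid <- zoo::na.locf(zoo::na.locf(zoo::zoo(xmid), na.rm = FALSE),
                         fromLast = TRUE)
    up <- env$mid > as.numeric(xmid)
    flips <- which(diff(up) != 0)
    if (length(flips)) {
      events <- data.frame(
        kind = ifelse(diff(up)[flips] > 0, "onset", "offset"),
        t = env$t[flips + 1])
      mode <- "branch"
    }
  }
  if (nrow(events) == 0) {
    out <- data.frame(kind = character(0), t = numeric(0))
  } else {
    out <- events[order(events$t), , drop = FALSE]
  }
  # attach path coordinates at event times
  if (model == "epileptor") {
    path <- project_path(traj)
    out$mu <- stats::approx(path$t, path$mu, out$t)$y
    out$mbar <- stats::approx(path$t, path$mbar, out$t)$y
  } else {
    path <- dtb_path(attr(traj, "params"), traj)
    out$mu1 <- stats::approx(path$t, path$mu1, out$t)$y
    out$nu <- stats::approx(path$t, path$nu, out$t)$y
  }
  attr(out, "mode") <- mode
  attr(out, "envelope") <- env
  out
}

# Hysteresis threshold crossings of the envelope amplitude.
envelope_events <- function(env, amp_on, amp_off) {
  state <- NA  # TRUE = ictal
  kinds <- character(0); times <- numeric(0)
  for (i in seq_len(nrow(env))) {
    a <- env$amp[i]
    if (is.na(state)) {
      if (a < amp_off) state <- FALSE else if (a > amp_on) state <- TRUE
    } else if (!state && a > amp_on) {
      state <- TRUE; kinds <- c(kinds, "onset"); times <- c(times, env$t[i])
    } else if (state && a < amp_off) {
      state <- FALSE; kinds <- c(kinds, "offset"); times <- c(times, env$t[i])
    }
  }
  data.frame(kind = kinds, t = times)
}

# Pair onset/offset events into complete bursts, dropping the first
# complete burst as initial-condition transient when more than one exists.
burst_pairs <- function(events, drop_first = TRUE, merge_gap = 0) {
  on <- events[events$kind == "onset", ]
  off <- events[events$kind == "offset", ]
  pairs <- list()
  for (i in seq_len(nrow(on))) {
    j <- which(off$t > on$t[i])
    if (length(j)) {
      j <- j[1]
      if (i < nrow(on) && on$t[i + 1] < off$t[j]) next
      pairs[[length(pairs) + 1]] <- list(onset = on[i, ], offset = off[j, ])
    }
  }
  if (merge_gap > 0) pairs <- merge_episodes(pairs, merge_gap)
  if (drop_first && length(pairs) > 1) pairs <- pairs[-1]
  pairs
}

# Near the end of a seizure the path can re-cross the Hopf line several
# times (intermediate-subsystem spikes), splitting one seizure into short
# oscillation episodes. Episodes separated by less than merge_gap are one
# seizure: first onset, last offset.
merge_episodes <- function(pairs, merge_gap) {
  if (length(pairs) < 2) return(pairs)
  out <- list(pairs[[1]])
  for (p in pairs[-1]) {
    prev <- out[[length(out)]]
    if (p$onset$t - prev$offset$t < merge_gap) {
      prev$offset <- p$offset
      out[[length(out)]] <- prev
    } else {
      out[[length(out) + 1]] <- p
    }
  }
  out
}

#' Classify a burster by its onset/offset bifurcation pair
#'
#' Assigns the dynamotype label of a full-Epileptor bursting trajectory.
#' Onset type: a finite-amplitude jump with a DC (baseline) shift of the
#' fast variable marks a saddle-node (SN) onset; amplitude growing
#' continuously from zero with no baseline shift marks a supercritical
#' Hopf (SupH) onset. Offset type: inter-peak intervals stretching while
#' the amplitude stays finite marks a saddle-homoclinic (SH) offset;
#' amplitude shrinking toward zero at the Hopf line `mbar = -N` marks a
#' SupH offset. Each timeseries diagnostic is cross-checked against the
#' nearest analytic bifurcation curve at the event's path location;
#' conflicting diagnostics yield the label `"ambiguous"` with both
#' candidates reported. Non-oscillating branch alternation is SN/SN.
#'
#' @param traj a full-Epileptor `dyn_trajectory`.
#' @param curves a [bifurcation_set()] for the trajectory's fast
#'   coefficients (built automatically if omitted).
#' @param events output of [detect_transitions()] (computed if omitted).
#' @param envelope_window,amp_on,amp_off forwarded to
#'   [detect_transitions()] when `events` is missing.
#' @return An object of class `burster_classification`: list with
#'   `onset_type`, `offset_type`, `label`, `events`, and a `diagnostics`
#'   list (DC shifts, amplitude ratios, period trend, event path
#'   locations, curve distances).
#' @export
classify_burster <- function(traj, curves = NULL, events = NULL,
                             envelope_window = 50, amp_on = 0.5,
                             amp_off = 0.2, merge_gap = 250) {
  stopifnot(inherits(traj, "dyn_trajectory"),
            identical(attr(traj, "model"), "epileptor"))
  params <- attr(traj, "params")
  fpb <- fast_params_from_epileptor(params, 0, 0)
  if (is.null(curves)) curves <- bifurcation_set(fpb)
  if (is.null(events))
    events <- detect_transitions(traj, envelope_window, amp_on, amp_off)
  env <- attr(events, "envelope")
  mode <- attr(events, "mode")

  if (nrow(events) == 0)
    stop("no onset/offset events detected; not a bursting trajectory")

  pairs <- burst_pairs(events, merge_gap = merge_gap)
  if (length(pairs) == 0)
    stop("no complete burst (onset followed by offset) detected")

  if (identical(mode, "branch")) {
    dc <- stats::median(vapply(pairs, function(pr) {
      i_on <- which(env$t >= pr$onset$t)[1]
      pre <- env$mid[max(1, i_on - 90):max(1, i_on - 60)]
      post <- env$mid[env$t >= pr$onset$t + 60 & env$t <= pr$onset$t + 90]
      abs(mean(post) - mean(pre))
    }, 0))
    out <- list(onset_type = "SN", offset_type = "SN", label = "SN/SN",
                events = events,
                diagnostics = list(mode = "branch",
                                   n_bursts = length(pairs),
                                   dc_shift_onset = dc))
    class(out) <- "burster_classification"
    return(out)
  }

  sn_mu <- curves$sn$sn_minus$mu
  hopf_mbar <- curves$hopf$mbar

  # spike-smoothed path ordinate, for the Hopf-crossing test at offsets
  path <- project_path(traj, params)
  mb_s <- block_median(path$t, path$mbar, block = 1)
  mb_s$v <- as.numeric(zoo::rollmedian(zoo::zoo(mb_s$v),
                                       k = 41, fill = "extend"))

  per_burst <- lapply(pairs, function(pr) {
    t_on <- pr$onset$t; t_off <- pr$offset$t
    ict <- env$t > t_on & env$t < t_off
    amp_max <- max(env$amp[ict])
    w <- 30  # time units flanking the events for baseline/amplitude reads
    mid_pre <- mean(env$mid[env$t >= t_on - 2 * w & env$t <= t_on - w])
    mid_post <- mean(env$mid[env$t >= t_on + w & env$t <= t_on + 2 * w])
    amp_pre_off <- mean(env$amp[env$t >= t_off - 2 * w & env$t <= t_off - w])
    # rise time: envelope from amp_on to 80% of burst maximum
    e_in <- env[ict, ]
    i80 <- which(e_in$amp >= 0.8 * amp_max)[1]
    rise <- if (is.na(i80)) Inf else e_in$t[i80] - t_on
    # inter-peak interval trend near the offset
    ipi <- ipi_trend(traj, t_on, t_off)
    # does the (smoothed) path ordinate reach the stable side of the Hopf
    # line around the offset? It must for a SupH offset; for a SH offset
    # the cycle still exists, so the path stays on the unstable side.
    near <- mb_s$t >= t_off - 150 & mb_s$t <= t_off + 100
    cross <- any(mb_s$v[near] < hopf_mbar)
    list(dc_shift_onset = abs(mid_post - mid_pre),
         rise_time = rise, amp_max = amp_max,
         offset_amp_ratio = amp_pre_off / amp_max,
         ipi_ratio = ipi,
         offset_hopf_cross = as.numeric(cross),
         onset_mu = pr$onset$mu, onset_mbar = pr$onset$mbar,
         offset_mu = pr$offset$mu, offset_mbar = pr$offset$mbar)
  })
  med <- function(f) stats::median(vapply(per_burst, `[[`, 0, f))

  diag <- list(
    mode = "envelope", n_bursts = length(per_burst),
    dc_shift_onset = med("dc_shift_onset"),
    rise_time = med("rise_time"),
    offset_amp_ratio = med("offset_amp_ratio"),
    ipi_ratio = med("ipi_ratio"),
    offset_hopf_cross = med("offset_hopf_cross") > 0.5,
    onset_mu = med("onset_mu"), onset_mbar = med("onset_mbar"),
    offset_mu = med("offset_mu"), offset_mbar = med("offset_mbar"))
  diag$onset_dist_sn <- abs(diag$onset_mu - sn_mu)
  diag$onset_dist_hopf <- abs(diag$onset_mbar - hopf_mbar)
  diag$offset_dist_hopf <- abs(diag$offset_mbar - hopf_mbar)
  diag$offset_dist_sh <- if (!is.null(curves$sh) && nrow(curves$sh))
    min(sqrt((curves$sh$mu - diag$offset_mu)^2 +
             (curves$sh$mbar - diag$offset_mbar)^2)) else NA_real_

  # Onset: finite jump with a DC shift (SN) vs growth from zero (SupH),
  # cross-checked against the nearer of the SN- line and the Hopf line.
  onset_ts <- if (diag$dc_shift_onset > 0.5) "SN" else "SupH"
  onset_cv <- if (diag$onset_dist_sn <= diag$onset_dist_hopf) "SN" else "SupH"
  onset <- if (onset_ts == onset_cv) onset_ts else "ambiguous"

  # Offset: diverging inter-peak interval (SH) vs amplitude dying on the
  # Hopf line (SupH); cross-checked against the curves at the offset path
  # point — the SH polyline when attached, otherwise whether the smoothed
  # path actually crosses the Hopf line there.
  offset_ts <- if (diag$ipi_ratio > 1.25) "SH" else "SupH"
  offset_cv <- if (!is.na(diag$offset_dist_sh)) {
    if (diag$offset_dist_hopf < diag$offset_dist_sh) "SupH" else "SH"
  } else if (diag$offset_hopf_cross) "SupH" else "SH"
  offset <- if (offset_ts == offset_cv) offset_ts else "ambiguous"

  label <- if (onset == "ambiguous" || offset == "ambiguous") {
    diag$candidates <- c(onset_ts = onset_ts, onset_curve = onset_cv,
                         offset_ts = offset_ts, offset_curve = offset_cv)
    "ambiguous"
  } else paste0(onset, "/", offset)

  structure(list(onset_type = onset, offset_type = offset, label = label,
                 events = events, diagnostics = diag),
            class = "burster_classification")
}

# Ratio of the last inter-peak interval of the ictal segment to the median
# interval: >> 1 when the period diverges toward a homoclinic offset.
ipi_trend <- function(traj, t_on, t_off) {
  seg <- traj$time > t_on & traj$time < t_off
  x <- traj$x1[seg]; tt <- traj$time[seg]
  if (length(x) < 10) return(1)
  pk <- which(diff(sign(diff(x))) == -2) + 1
  pk <- pk[x[pk] > stats::quantile(x, 0.6)]  # prominent maxima only
  if (length(pk) < 4) return(1)
  ipi <- diff(tt[pk])
  ipi <- ipi[ipi > 2 * (tt[2] - tt[1])]
  if (length(ipi) < 3) return(1)
  utils::tail(ipi, 1) / stats::median(ipi)
}

#' @export
print.burster_classification <- function(x, ...) {
  cat(sprintf("Burster class: %s  (%d complete burst(s), %s detection)\n",
              x$label, x$diagnostics$n_bursts, x$diagnostics$mode))
  if (!is.null(x$diagnostics$onset_mu))
    cat(sprintf("  onset  at (mu, mbar) = (%.3f, %.3f); offset at (%.3f, %.3f)\n",
                x$diagnostics$onset_mu, x$diagnostics$onset_mbar,
                x$diagnostics$offset_mu, x$diagnostics$offset_mbar))
  invisible(x)
}

# Arc-length resampling of a polyline to n points.
resample_polyline <- function(xy, n = 400) {
  d <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(d))
  if (s[length(s)] == 0) return(xy[rep(1, n), , drop = FALSE])
  grid <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, xy[, 1], grid)$y, stats::approx(s, xy[, 2], grid)$y)
}

# Symmetric Hausdorff distance between two resampled polylines.
polyline_distance <- function(a, b) {
  nn <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i)
      sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2)), numeric(1))
  }
  max(max(nn(a, b)), max(nn(b, a)))
}

#' Sweep the epileptogenicity and measure its effect on the path
#'
#' Runs the model at each `x0`, projects the path, detects transitions and
#' measures per-burst interictal/ictal durations and (when the
#' intermediate subsystem is active) the number of intermediate spikes per
#' burst. The projected path of the last complete burst is arc-length
#' resampled and compared across `x0` values by symmetric Hausdorff
#' distance, reported relative to the path's bounding-box diagonal: with
#' the intermediate subsystem silenced, `x0` changes the speed along the
#' path, not the path itself.
#'
#' @param base_params an [epileptor_params()] object (its `x0` is
#'   overridden per sweep value).
#' @param x0_values numeric vector of epileptogenicities.
#' @param t_span,opts forwarded to [integrate_model()].
#' @return List with `summary` (data frame: `x0`, `interictal`, `ictal`,
#'   `spikes_per_burst`, `no_bursting`), `paths` (list of per-burst path
#'   polylines), and `max_path_distance_rel` (max pairwise relative
#'   Hausdorff distance across the bursting sweep values).
#' @export
x0_sweep <- function(base_params, x0_values, t_span = c(0, 16000),
                     opts = solve_options()) {
  stopifnot(inherits(base_params, "epileptor_params"))
  res <- lapply(x0_values, function(x0) {
    args <- unclass(base_params); args$x0 <- x0
    params <- do.call(epileptor_params, args)
    traj <- integrate_model("epileptor", params,
                            epileptor_rest_state(params), t_span, opts)
    ev <- detect_transitions(traj)
    pairs_all <- burst_pairs(ev, drop_first = FALSE, merge_gap = 250)
    if (length(pairs_all) < 2)
      return(list(x0 = x0, no_bursting = TRUE, interictal = NA,
                  ictal = NA, spikes = NA, loop = NULL))
    pairs <- pairs_all[-1]  # drop the initial-condition transient
    ictal <- stats::median(vapply(pairs, function(p) p$offset$t - p$onset$t,
                                  0))
    inter <- stats::median(vapply(seq_along(pairs_all)[-1], function(i)
      pairs_all[[i]]$onset$t - pairs_all[[i - 1]]$offset$t, 0))
    # intermediate spikes: upward zero-crossings of x2 during the ictal
    spikes <- stats::median(vapply(pairs, function(p) {
      seg <- traj$time > p$onset$t & traj$time < p$offset$t
      sum(diff(traj$x2[seg] > 0) == 1)
    }, 0))
    # closed path loop of one full cycle (second-to-last onset to the next)
    path <- project_path(traj, params)
    ons <- vapply(pairs_all, function(p) p$onset$t, 0)
    last <- if (length(pairs) > 1) pairs[[length(pairs) - 1]]
            else pairs[[length(pairs)]]
    nxt <- ons[ons > last$onset$t + 1][1]
    tmax <- if (is.finite(nxt)) nxt else max(path$t)
    loop <- path[path$t >= last$onset$t & path$t <= tmax, c("mu", "mbar")]
    list(x0 = x0, no_bursting = FALSE, interictal = inter, ictal = ictal,
         spikes = spikes, loop = as.matrix(loop))
  })
  summary <- data.frame(
    x0 = x0_values,
    interictal = vapply(res, function(r) as.numeric(r$interictal), 0),
    ictal = vapply(res, function(r) as.numeric(r$ictal), 0),
    spikes_per_burst = vapply(res, function(r) as.numeric(r$spikes), 0),
    no_bursting = vapply(res, function(r) r$no_bursting, TRUE))
  loops <- lapply(res, `[[`, "loop")
  ok <- !vapply(loops, is.null, TRUE)
  maxrel <- NA_real_
  if (sum(ok) >= 2) {
    rl <- lapply(loops[ok], resample_polyline)
    all_pts <- do.call(rbind, rl)
    extent <- sqrt(diff(range(all_pts[, 1]))^2 + diff(range(all_pts[, 2]))^2)
    dists <- c()
    idx <- which(ok)
    for (i in seq_along(rl)) for (j in seq_len(i - 1))
      dists <- c(dists, polyline_distance(rl[[i]], rl[[j]]))
    maxrel <- max(dists) / extent
  }
  list(summary = summary, paths = loops, max_path_distance_rel = maxrel)
}
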