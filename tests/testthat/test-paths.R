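test_that("path projection is the exact algebraic image of (z, x2)", {
  p <- epileptor_params(x0 = -2, m = 0.3, alpha = -1)
  tr <- integrate_model("epileptor", p, epileptor_rest_state(p), c(0, 200))
  path <- project_path(tr, p)
  expect_identical(path$mu, p$Irest1 - tr$z)
  expect_identical(path$mbar,
                   0.6 * p$alpha * (tr$z - 4)^2 + p$m - tr$x2)
  # z = Irest1 gives mu = 0 by construction
  expect_equal(path$mu[which.min(abs(tr$z - p$Irest1))],
               p$Irest1 - tr$z[which.min(abs(tr$z - p$Irest1))])
})

test_that("silencing the intermediate subsystem removes path spikes", {
  # spikes appear as fast large-amplitude mbar excursions inside the ictal
  # segment (away from the onset/offset jumps)
  ictal_inc <- function(tr) {
    ev <- detect_transitions(tr)
    pr <- dynamotype:::burst_pairs(ev, merge_gap = 250)[[1]]
    path <- project_path(tr)
    seg <- path$t > pr$onset$t + 60 & path$t < pr$offset$t - 60
    max(abs(diff(path$mbar[seg], lag = 20)))
  }
  expect_lt(ictal_inc(run_preset("sn_sh", t_span = c(0, 9000))), 0.3)
  expect_gt(ictal_inc(run_preset("sn_suph", t_span = c(0, 9000))), 1)
})

test_that("transition detection on a synthetic envelope signal", {
  # two sine bursts of known extent on a flat baseline
  t <- seq(0, 4000, by = 0.1)
  x <- rep(-1.5, length(t))
  for (w in list(c(800, 1400), c(2400, 3000))) {
    i <- t >= w[1] & t <= w[2]
    x[i] <- -0.2 + 1.2 * sin(2 * pi * t[i] / 8)
  }
  tr <- structure(data.frame(time = t, x1 = x, y1 = 0, z = 3.3, x2 = -1,
                             y2 = 0, u = 0),
                  class = c("dyn_trajectory", "data.frame"),
                  model = "epileptor", params = epileptor_params())
  ev <- detect_transitions(tr)
  expect_equal(attr(ev, "mode"), "envelope")
  expect_equal(sum(ev$kind == "onset"), 2)
  expect_equal(sum(ev$kind == "offset"), 2)
  expect_equal(ev$t[ev$kind == "onset"], c(800, 2400), tolerance = 40)
  expect_equal(ev$t[ev$kind == "offset"], c(1400, 3000), tolerance = 40)
})

test_that("a constant trajectory yields no events", {
  t <- seq(0, 2000, by = 0.1)
  tr <- structure(data.frame(time = t, x1 = -1.6, y1 = 0, z = 3, x2 = -1,
                             y2 = 0, u = 0),
                  class = c("dyn_trajectory", "data.frame"),
                  model = "epileptor", params = epileptor_params())
  ev <- detect_transitions(tr)
  expect_equal(nrow(ev), 0)
  expect_error(classify_burster(tr, events = ev), "no onset/offset")
})

test_that("square-wave preset: SN onset on the fold, SH offset", {
  tr <- run_preset("sn_sh")
  cls <- classify_burster(tr)
  expect_equal(cls$label, "SN/SH")
  # detected onsets sit within 5% of the analytic SN- value mu = 5/27
  expect_lt(abs(cls$diagnostics$onset_mu - 5 / 27), 0.05 * 5 / 27 + 0.02)
  expect_gt(cls$diagnostics$dc_shift_onset, 0.5)
  expect_gt(cls$diagnostics$ipi_ratio, 1.25)
  # hysteresis: onset and offset map locations are distinct
  expect_gt(abs(cls$diagnostics$onset_mu - cls$diagnostics$offset_mu), 0.1)
})

test_that("intermediate drive converts the offset to supercritical Hopf", {
  cls <- classify_burster(run_preset("sn_suph"))
  expect_equal(cls$label, "SN/SupH")
  expect_true(cls$diagnostics$offset_hopf_cross)
})

test_that("depolarization-block preset alternates branches without spikes", {
  cls <- classify_burster(run_preset("sn_sn"))
  expect_equal(cls$label, "SN/SN")
  expect_equal(cls$diagnostics$mode, "branch")
})

test_that("inverted path curvature yields a supercritical-Hopf onset", {
  cls <- classify_burster(run_preset("suph_sh"))
  expect_equal(cls$label, "SupH/SH")
  expect_lt(cls$diagnostics$dc_shift_onset, 0.5)
  # onset mbar within 5% of the Hopf line -N = 1 (slow-passage lag allowed
  # in mu, the ordinate is what defines this onset)
  expect_lt(abs(cls$diagnostics$onset_mbar - 1), 0.3)
})

test_that("epileptogenicity sweep: speed changes, path does not (much)", {
  sw <- x0_sweep(preset_params("sn_sh"), c(-2.05, -1.95, -1.85),
                 t_span = c(0, 12000))
  expect_true(all(!sw$summary$no_bursting))
  # interictal duration decreases monotonically as x0 increases
  expect_true(all(diff(sw$summary$interictal) < 0))
  # burst loops nearly coincide; the residual sits at the onset corner
  expect_lt(sw$max_path_distance_rel, 0.05)
  expect_true(all(sw$summary$spikes_per_burst == 0))
})

test_that("beyond the epileptogenicity threshold the sweep flags rest", {
  sw <- x0_sweep(preset_params("sn_sh"), c(-2.2), t_span = c(0, 8000))
  expect_true(sw$summary$no_bursting[1])
})

test_that("x0 modulates the intermediate spike count when the drive is on", {
  sw <- x0_sweep(preset_params("sn_suph"), c(-2.0, -1.8),
                 t_span = c(0, 12000))
  expect_true(all(!sw$summary$no_bursting))
  expect_true(all(sw$summary$spikes_per_burst > 0))
  expect_false(sw$summary$spikes_per_burst[1] ==
                 sw$summary$spikes_per_burst[2])
})

test_that("DTB burster performs the rest -> SN -> cycle -> SH -> rest loop", {
  tr <- run_preset("dtb_sn_sh")
  ev <- detect_transitions(tr, envelope_window = 50, amp_on = 0.3,
                           amp_off = 0.1)
  expect_equal(attr(ev, "mode"), "envelope")
  on <- ev[ev$kind == "onset", ]
  off <- ev[ev$kind == "offset", ]
  expect_gte(nrow(on), 3)
  p <- attr(tr, "params")
  fold_mu1 <- local({
    # fold where the resting (right) branch meets the middle branch
    xf <- sqrt(p$mu2 / 3)
    xf^3 - p$mu2 * xf
  })
  # onsets at the saddle-node of the resting branch
  expect_lt(abs(stats::median(on$mu1) - fold_mu1), 0.05 * abs(fold_mu1))
  # offsets inside the three-fixed-point wedge (cycle meets the saddle)
  expect_true(all(off$mu1 > fold_mu1))
  # projected path is contained in the straight line exactly
  path <- dtb_path(p, tr)
  expect_equal(path$nu, p$nu_0 + p$d_nu * (path$mu1 - p$mu1_0) / p$d_mu1,
               tolerance = 1e-12)
})
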