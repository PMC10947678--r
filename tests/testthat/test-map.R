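test_that("limit-cycle statistics distinguish rest from oscillation", {
  st <- limit_cycle_stats(default_fast(mu = 1, mbar = 0.5))
  expect_true(st$converged_to_fp)
  expect_lt(st$amplitude, 1e-3)
  expect_equal(st$frequency, 0)

  st <- limit_cycle_stats(default_fast(mu = -0.4, mbar = 1.3))
  expect_false(st$converged_to_fp)
  expect_gt(st$amplitude, 1)
  expect_gt(st$frequency, 0.1)
})

test_that("amplitude shrinks to zero approaching the Hopf line from above", {
  amps <- vapply(c(1.3, 1.1, 1.01, 1.002, 1.001),
                 function(mb) limit_cycle_stats(default_fast(-0.4, mb))$amplitude,
                 numeric(1))
  expect_true(all(diff(amps) < 0))
  expect_lt(amps[5], 0.2)
  # square-root scaling holds in the immediate vicinity of the Hopf line
  # (farther out the cycle inflates to relaxation size)
  expect_equal(amps[5] / amps[4], sqrt(0.001 / 0.002), tolerance = 0.1)
})

test_that("frequency decreases toward the saddle-homoclinic boundary", {
  mus <- seq(-0.85, -0.45, by = 0.1)
  fr <- vapply(mus,
               function(mu) limit_cycle_stats(default_fast(mu, 1.3))$frequency,
               numeric(1))
  expect_true(all(diff(fr) > 0))  # increasing away from the SH boundary
  expect_lt(fr[1], 0.1)
})

test_that("dominant_frequency recovers a known tone under the Hann window", {
  t <- seq(0, 300, by = 0.1)
  x <- 1.5 * sin(2 * pi * 0.23 * t) + 0.2
  expect_equal(dominant_frequency(x, 0.1), 0.23, tolerance = 1e-3)
  expect_equal(dominant_frequency(rep(2, 1000), 0.1), 0)
})

test_that("map builder is deterministic and census finds five regions", {
  fpb <- default_fast()
  g1 <- build_map(fpb, c(-1.975, 0.975), c(-2.95, 1.95),
                  resolution = c(12, 14))
  g2 <- build_map(fpb, c(-1.975, 0.975), c(-2.95, 1.95),
                  resolution = c(12, 14))
  expect_identical(g1$amplitude, g2$amplitude)
  expect_identical(g1$frequency, g2$frequency)
  cen <- region_census(g1)
  expect_lte(nrow(cen), 5)
  expect_true(all(cen$n_stable_fp <= cen$n_fp))
  expect_true(all(cen$n_fp %in% c(1L, 3L)))
})

test_that("classify_region resolves the canonical configurations", {
  # bistable rest + limit cycle (seizure regime)
  yl <- classify_region(default_fast(-0.4, 1.3))
  expect_equal(yl$n_fp, 3)
  expect_equal(yl$n_stable_fp, 1)
  expect_true(yl$has_stable_lc)
  # two stable fixed points, no cycle
  gr <- classify_region(default_fast(0, 0))
  expect_equal(gr$n_fp, 3)
  expect_equal(gr$n_stable_fp, 2)
  expect_false(gr$has_stable_lc)
  # limit cycle as the only stable attractor
  v <- classify_region(default_fast(0.5, 1.5))
  expect_equal(v$n_fp, 1)
  expect_equal(v$n_stable_fp, 0)
  expect_true(v$has_stable_lc)
})

test_that("SH inference interpolates the oscillation boundary", {
  fpb <- default_fast()
  g <- build_map(fpb, c(-1.3, 0.1), c(1.05, 1.55), resolution = c(15, 5))
  sh <- infer_sh_curve(g)
  expect_gt(nrow(sh), 2)
  # boundary moves rightward (larger mu) for larger mbar
  expect_true(all(diff(sh$mu) >= 0))
  expect_gt(sh$mu[nrow(sh)], sh$mu[1])
  # first vertex close to the Takens-Bogdanov point
  tb <- tb_point(fpb)
  expect_lt(abs(sh$mu[1] - tb[["mu"]]), diff(g$mu_values[1:2]) + 1e-9)
  expect_lt(abs(sh$mbar[1] - tb[["mbar"]]), diff(g$mbar_values[1:2]) + 1e-9)
})

test_that("an all-rest grid has near-zero amplitude and warns on SH", {
  g <- build_map(default_fast(), c(0.6, 0.9), c(-0.5, 0.3),
                 resolution = c(3, 3),
                 protocol = map_protocol(t_total = 120, t_discard = 60))
  expect_true(all(g$converged_to_fp))
  expect_true(all(g$amplitude < 1e-3))
  expect_warning(sh <- infer_sh_curve(g), "no oscillatory cells")
  expect_equal(nrow(sh), 0)
})

test_that("the DTB layer map shows the same qualitative structure", {
  g <- build_map(list(mu2 = 0.07), c(-0.009, 0.0), c(0.02, 0.1),
                 resolution = c(6, 3), model = "dtb_fast",
                 protocol = dtb_map_protocol(t_total = 800, t_discard = 300))
  # oscillatory cells exist (left of the fold) and rest cells too
  expect_true(any(!g$converged_to_fp))
  expect_true(any(g$converged_to_fp))
  expect_true(all(g$amplitude[!g$converged_to_fp] > 1e-3))
})
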