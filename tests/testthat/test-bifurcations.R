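test_that("fixed points at (mu, mbar) = (0, 0) match the factored roots", {
  pts <- fixed_points(default_fast(0, 0))
  expect_equal(nrow(pts), 3)
  expect_equal(pts$x, c((-1 - sqrt(5)) / 2, -1, 1 / sqrt(5)),
               tolerance = 1e-10)
  expect_equal(pts$stability,
               c("stable-node", "saddle", "stable-focus"))
  expect_equal(pts$y, -(1 - 5 * pts$x^2) / (-1), tolerance = 1e-10)
})

test_that("branches merge at the seam when mu = nu*y0/N with mbar < 0", {
  pts <- fixed_points(default_fast(mu = -1, mbar = -1))
  expect_true(any(pts$branch == "boundary"))
  expect_equal(pts$stability[pts$branch == "boundary"], "non-hyperbolic")
})

test_that("far above the fold structure a single upper fixed point remains", {
  pts <- fixed_points(default_fast(mu = 1, mbar = 0.5))
  expect_equal(nrow(pts), 1)
  expect_true(pts$x > 0)
  expect_match(pts$stability, "^stable")
})

test_that("Jacobian entries follow the piecewise formula", {
  fp <- default_fast(0, 0.7)
  J <- jacobian_fast(fp, 1e-9)  # x = 0+ uses the mbar branch
  expect_equal(J, matrix(c(0.7, 2 * (-5) * 1e-9, 1, -1), 2, 2))
  set.seed(5)
  for (i in 1:20) {
    p <- random_fast()
    x <- -runif(1, 0.1, 2)
    J <- jacobian_fast(p, x)
    det_expanded <- x * (3 * p$a * p$N * x + 2 * p$N * (p$b - p$nu * p$B / p$N))
    expect_equal(det(J), det_expanded, tolerance = 1e-10)
  }
})

test_that("saddle-node curves take their closed-form default values", {
  sn <- sn_curves(default_fast())
  expect_equal(sn$sn_minus$mu, 5 / 27, tolerance = 1e-12)
  expect_equal(sn$sn_minus$x_fold, -4 / 3, tolerance = 1e-12)
  expect_equal(sn$sn_zero$mu, -1, tolerance = 1e-12)
  expect_equal(sn$sn_plus$mu_of_mbar(2), -1.2, tolerance = 1e-12)
  expect_true(sn$sn_plus$mbar_valid(1))
  expect_false(sn$sn_plus$mbar_valid(-0.5))
})

test_that("Jacobian determinant vanishes on the saddle-node curves", {
  set.seed(9)
  for (i in 1:30) {
    p <- random_fast()
    sn <- sn_curves(p)
    Jm <- jacobian_fast(p, sn$sn_minus$x_fold)
    expect_equal(det(Jm), 0, tolerance = 1e-10)
    xf <- sn$sn_plus$x_fold_of_mbar(p$mbar)
    Jp <- jacobian_fast(p, xf)
    expect_equal(det(Jp), 0, tolerance = 1e-10)
  }
})

test_that("analytic folds agree with independent root-count bisection", {
  # brute-force oracle: bisect mu where the number of real roots of each
  # branch changes (polyroot-based counting, no shared formulas)
  # the root count also changes at the seam pseudo-fold mu = nu*y0/N, so
  # the bracket's inner end stays between the two boundaries
  set.seed(42)
  for (i in 1:200) {
    p <- random_fast()
    sn <- sn_curves(p)
    mu0 <- p$nu * p$y0 / p$N
    ref_m <- sn$sn_minus$mu
    mu_minus <- bisect_count_change(function(m) count_neg_roots(p, m),
                                    max(ref_m - 0.4, (ref_m + mu0) / 2),
                                    ref_m + 0.4)
    expect_equal(mu_minus, ref_m, tolerance = 1e-9)
    ref_p <- sn$sn_plus$mu_of_mbar(p$mbar)
    mu_plus <- bisect_count_change(function(m) count_pos_roots(p, m),
                                   ref_p - 0.4,
                                   min(ref_p + 0.4, (ref_p + mu0) / 2))
    expect_equal(mu_plus, ref_p, tolerance = 1e-9)
  }
})

test_that("the Hopf line sits at mbar = -N with no negative-branch Hopf", {
  hp <- hopf_curve(default_fast())
  expect_equal(hp$mbar, 1)
  expect_equal(sort(hp$neg_branch_candidates),
               sort((-2 * 3 + c(-1, 1) * sqrt(4 * 9 - 12 * (-1) * (-1))) / -6),
               tolerance = 1e-10)
  expect_true(all(hp$neg_branch_candidates >= 0))
  expect_false(hp$has_negative_branch_hopf)
  expect_true(hp$valid(-0.5))
  expect_false(hp$valid(-1.2))
})

test_that("on the Hopf line eigenvalues are purely imaginary", {
  for (mu in c(-1.0, -0.5, 0, 0.5)) {
    fp <- default_fast(mu = mu, mbar = 1)
    pts <- fixed_points(fp)
    up <- pts[which.max(pts$x), ]
    J <- jacobian_fast(fp, up$x)
    ev <- eigen(J, only.values = TRUE)$values
    expect_lt(max(abs(Re(ev))), 1e-10)
    expect_gt(max(abs(Im(ev))), 0)
  }
})

test_that("the Takens-Bogdanov point carries a double-zero Jacobian", {
  tb <- tb_point(default_fast())
  expect_equal(unname(tb), c(-1.05, 1, 0.1), tolerance = 1e-12)
  fp <- default_fast(mu = tb[["mu"]], mbar = tb[["mbar"]])
  J <- jacobian_fast(fp, tb[["x"]])
  expect_equal(sum(diag(J)), 0, tolerance = 1e-10)
  expect_equal(det(J), 0, tolerance = 1e-10)
  sn <- sn_curves(fp)
  expect_equal(sn$sn_plus$mu_of_mbar(tb[["mbar"]]), tb[["mu"]])
  expect_equal(hopf_curve(fp)$mbar, tb[["mbar"]])
})

test_that("fixed-point census changes by two across the SN- fold", {
  eps <- 1e-3
  inside <- local_region_config(default_fast(5 / 27 - eps, -1))
  outside <- local_region_config(default_fast(5 / 27 + eps, -1))
  expect_equal(inside$n_fp - outside$n_fp, 2)
  near <- local_region_config(default_fast(5 / 27 + 1e-10, -1))
  expect_true(near$on_curve)
})

test_that("cubic solver matches polyroot on random cubics", {
  set.seed(21)
  for (i in 1:100) {
    co <- runif(4, -3, 3)
    if (abs(co[1]) < 0.1) co[1] <- 0.5
    mine <- dynamotype:::solve_cubic_real(co[1], co[2], co[3], co[4])
    ref <- polyroot(rev(co))
    ref <- sort(Re(ref[abs(Im(ref)) < 1e-7]))
    expect_equal(length(mine), length(ref))
    if (length(ref)) expect_equal(mine, ref, tolerance = 1e-6)
  }
})
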