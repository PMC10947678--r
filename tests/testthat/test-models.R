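test_that("Epileptor derivatives match hand-computed values at the origin", {
  d <- epileptor_rhs(rep(0, 6), epileptor_params())
  expect_equal(d[1], 3.1)                 # y1 - 0 + 0 - z + Irest1
  expect_equal(d[2], 1)                   # y0
  expect_equal(d[3], 6.4 / 2857)          # (4*(0 + 1.6) - 0)/tau0
  expect_equal(d[4], 1.5)                 # Irest2 + 0 - 0.3*(0 - 3.5)
  expect_equal(d[5], 0.15)                # 6*(0 + 0.25)/tau2
  expect_equal(d[6], 0)
})

test_that("vector fields are continuous across their switch surfaces", {
  set.seed(11)
  for (i in 1:25) {
    p <- epileptor_params(m = runif(1, -8, 2), alpha = sample(c(-1, 1), 1))
    s <- runif(6, -2, 2)
    sl <- sr <- s; sl[1] <- -1e-12; sr[1] <- 1e-12
    expect_equal(epileptor_rhs(sl, p), epileptor_rhs(sr, p),
                 tolerance = 1e-9)
    sl <- sr <- s; sl[4] <- -0.25 - 1e-12; sr[4] <- -0.25 + 1e-12
    expect_equal(epileptor_rhs(sl, p), epileptor_rhs(sr, p),
                 tolerance = 1e-9)
    fp <- random_fast()
    expect_equal(fast_rhs(c(-1e-12, s[2]), fp), fast_rhs(c(1e-12, s[2]), fp),
                 tolerance = 1e-9)
  }
})

test_that("generalized x1 branch reduces to the printed model at alpha = 1", {
  # at alpha = 1 the x1 >= 0 branch is y1 + (m - x2 + 0.6*(z-4)^2)x1 ...
  s <- c(0.7, 0.2, 3.2, -0.8, 0.1, 0.05)
  p <- epileptor_params(m = 0.3)
  d <- epileptor_rhs(s, p)
  expect_equal(d[1],
               s[2] + (0.3 - s[4] + 0.6 * (s[3] - 4)^2) * s[1] - s[3] + 3.1)
})

test_that("fast subsystem examples and nullcline identity hold", {
  d <- fast_rhs(c(0, 0), fast_params(mu = -1, mbar = 0))
  expect_equal(d, c(-1, 1))
  set.seed(7)
  for (i in 1:20) {
    fp <- random_fast()
    x <- runif(1, -2, 2)
    y_null <- -(fp$y0 + fp$B * x^2) / fp$N
    expect_equal(fast_rhs(c(x, y_null), fp)[2], 0, tolerance = 1e-12)
  }
  # the vector field vanishes at every computed fixed point
  fp <- default_fast(mu = -0.3, mbar = 0.7)
  pts <- fixed_points(fp)
  for (i in seq_len(nrow(pts)))
    expect_equal(fast_rhs(c(pts$x[i], pts$y[i]), fp), c(0, 0),
                 tolerance = 1e-9)
})

test_that("DTB right-hand side follows the affine path parametrization", {
  p <- dtb_params()
  expect_equal(dtb_rhs(c(p$x0, 0.3, 1.2), p)[3], 0)  # dz = 0 at x = x0
  d <- dtb_rhs(c(0, 0, 2), p)
  expect_equal(d[1], 0)
  expect_equal(d[2], -(p$mu1_0 + p$d_mu1 * 2))
  # the projected path lies exactly on the straight line through
  # (mu1_0, nu_0) with direction (d_mu1, d_nu)
  z <- seq(-1, 5, length.out = 30)
  mu1 <- p$mu1_0 + p$d_mu1 * z
  nu <- p$nu_0 + p$d_nu * z
  if (p$d_mu1 != 0) {
    tpar <- (mu1 - p$mu1_0) / p$d_mu1
    expect_equal(nu, p$nu_0 + p$d_nu * tpar, tolerance = 1e-12)
  }
})

test_that("rhs rejects non-finite states", {
  expect_error(epileptor_rhs(c(NaN, 0, 0, 0, 0, 0), epileptor_params()),
               "diverged")
  expect_error(fast_rhs(c(Inf, 0), default_fast()), "diverged")
})

test_that("lfp is x2 - x1 and demands a full-model trajectory", {
  tr <- integrate_model("epileptor", epileptor_params(),
                        c(-1.5, -10, 3, 0, 0, 0), c(0, 5))
  expect_equal(lfp(tr), tr$x2 - tr$x1)
  ftr <- integrate_model("fast", default_fast(-0.4, 1.3), c(0.5, 0), c(0, 5))
  expect_error(lfp(ftr), "full-Epileptor")
})

test_that("compiled and R right-hand sides agree along trajectories", {
  # integrate the full model with the compiled derivatives and check the
  # R-level epileptor_rhs reproduces the numerical derivative pointwise
  p <- epileptor_params(x0 = -2, Irest2 = 0)
  tr <- integrate_model("epileptor", p, epileptor_rest_state(p), c(0, 400))
  s <- as.matrix(tr[, -1])
  set.seed(3)
  for (i in sample(50:nrow(tr) - 1, 12)) {
    num <- (s[i + 1, ] - s[i - 1, ]) / (tr$time[i + 1] - tr$time[i - 1])
    ana <- epileptor_rhs(s[i, ], p)
    expect_equal(unname(num), ana, tolerance = 5e-3)
  }
})
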