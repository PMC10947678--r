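# Shared fixtures: everything is generated in code at test time.

default_fast <- function(mu = 0, mbar = 0) fast_params(mu = mu, mbar = mbar)

# Random admissible fast-parameter draw for property tests: signs chosen so
# the negative-branch fold sits at x < 0 and the positive-branch fold at
# x >= 0, as in the default coefficient family.
random_fast <- function() {
  repeat {
    p <- list(nu = runif(1, 0.5, 1.5), a = runif(1, -2, -0.5),
              b = runif(1, 2, 4), B = runif(1, -6, -3),
              N = runif(1, -1.5, -0.5), y0 = runif(1, 0.5, 1.5),
              mbar = runif(1, 0.5, 3))
    c2 <- p$b - p$nu * p$B / p$N
    if (c2 < -0.1) {
      return(fast_params(mu = 0, mbar = p$mbar, nu = p$nu, a = p$a,
                         b = p$b, y0 = p$y0, B = p$B, N = p$N))
    }
  }
}

# Independent root-count oracles (polyroot-based, no closed forms shared
# with the implementation).
count_neg_roots <- function(fp, mu) {
  # a x^3 + c2 x^2 + c0 = 0, roots with x < 0
  c2 <- fp$b - fp$nu * fp$B / fp$N
  c0 <- mu - fp$nu * fp$y0 / fp$N
  r <- polyroot(c(c0, 0, c2, fp$a))
  sum(abs(Im(r)) < 1e-7 & Re(r) < -1e-9)
}

count_pos_roots <- function(fp, mu, mbar = fp$mbar) {
  qa <- -fp$nu * fp$B / fp$N
  c0 <- mu - fp$nu * fp$y0 / fp$N
  r <- polyroot(c(c0, mbar, qa))
  sum(abs(Im(r)) < 1e-7 & Re(r) > -1e-12)
}

# Bisect mu for a change in an integer-valued count function.
bisect_count_change <- function(count_fun, lo, hi, iter = 60) {
  clo <- count_fun(lo)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (count_fun(mid) == clo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
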