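# Shared helpers for the test suite. Oracles here are deliberately
# independent of the package internals they check.

# Brute-force bisection for the n-th root of tan(q) = -alpha*q, working
# directly on tan over ((n-1/2)pi, n pi). Slow and simple.
bisect_root <- function(alpha, n, iters = 200) {
  f <- function(q) tan(q) + alpha * q
  lo <- (n - 0.5) * pi + 1e-12
  hi <- n * pi - 1e-12
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# A contact system whose V_F/V_P matches the empirical value implied by
# the packaged parameter table (alpha * K_P/F ~ 250), for tests that use
# its printed alpha-K pairs.
empirical_system <- function(vf_vp = 250.1) {
  film <- film_spec()
  contact_system(film, food_volume_ml = vf_vp * film$area_cm2 * film$thickness_cm)
}

# Noiseless migration curve at the default sampling grid.
model_curve <- function(D, alpha, times = default_times(), L = 8e-3) {
  data.frame(time_h = times,
             mr_percent = as.numeric(migration_profile(times, D, alpha, L)))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
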