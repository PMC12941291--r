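test_that("series vanishes at t = 0 and its coefficients sum to one", {
  expect_identical(as.numeric(series_fraction(8e-11, 0, 8e-3, 0.328)), 0)
  # truncation adequacy: sum_n 2a(1+a)/(1+a+a^2 q_n^2) -> 1; the tail of
  # an N-term sum is bounded by ~ 2(1+a)/(a pi^2 N)
  for (alpha in c(0.05, 0.3, 1, 3)) {
    rs <- solve_roots(alpha, 5000)
    s <- sum(migrisk:::series_coefficients(rs))
    expect_lt(abs(s - 1), 2 * (1 + alpha) / (alpha * pi^2 * 5000) * 1.5)
    expect_lt(abs(s - 1), 1e-3)
  }
})

test_that("long-time limit reaches one", {
  v <- series_fraction(1, 10, 1, 0.328)  # D*t/L^2 = 10
  expect_equal(as.numeric(v), 1, tolerance = 1e-10)
})

test_that("series is monotone in time and in D, and bounded in [0, 1]", {
  t_s <- 10^seq(1, 6, length.out = 40)
  for (alpha in c(0.05, 1, 10)) {
    rs <- solve_roots(alpha, 200)
    v <- as.numeric(series_fraction(8e-11, t_s, 8e-3, alpha, roots = rs))
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))
    vD <- vapply(c(1e-12, 5e-12, 2e-11, 1e-10), function(D)
      as.numeric(series_fraction(D, 3600, 8e-3, alpha, roots = rs)),
      numeric(1))
    expect_true(all(diff(vD) >= 0))
  }
})

test_that("series coefficients approach the infinite-bath coefficients at huge alpha", {
  rs <- solve_roots(1e6, 10)
  co <- migrisk:::series_coefficients(rs)
  n <- 1:10
  expect_rel(co, 8 / ((2 * n - 1)^2 * pi^2), 1e-4)
})

test_that("finite-bath series at alpha = 1e6 matches the infinite-bath closed form", {
  tau <- 10^seq(-3, 1, length.out = 20)
  rs <- solve_roots(1e6, 200)
  fin <- as.numeric(series_fraction(1, tau, 1, 1e6, roots = rs))
  inf <- infinite_bath_fraction(1, tau, 1)
  expect_lt(max(abs(fin - inf)), 1e-3)
})

test_that("severe truncation on a fast-varying curve is flagged", {
  rs <- solve_roots(0.328, 5)
  v <- series_fraction(8e-11, 60, 8e-3, 0.328, roots = rs, n_terms = 5)
  expect_true(attr(v, "underresolved"))
  v2 <- series_fraction(8e-11, 3600 * 24, 8e-3, 0.328)
  expect_false(attr(v2, "underresolved"))
})

test_that("model migration curve composes plateau and series", {
  expect_equal(as.numeric(migration_profile(0, 8e-11, 0.328)), 0)
  # long-time plateau at 100 * alpha / (1 + alpha)
  plateau <- as.numeric(migration_profile(1e6, 9.53e-11, 3.293))
  expect_equal(plateau, 76.7, tolerance = 1e-3)
  v <- as.numeric(migration_profile(c(0, 0.5, 2, 8, 24, 72), 8e-11, 0.328))
  expect_true(all(diff(v) > 0))
  expect_lt(v[length(v)], 100 * equilibrium_fraction(0.328))
})
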