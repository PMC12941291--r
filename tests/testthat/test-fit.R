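test_that("noiseless curves are refit to the generating parameters", {
  sys <- contact_system()
  d <- model_curve(8.00e-11, 0.328)
  fit <- fit_migration(mr_percent ~ time_h, d, sys)
  expect_lt(abs(coef(fit)[["D"]] - 8.00e-11) / 8.00e-11, 0.005)
  expect_lt(abs(coef(fit)[["alpha"]] - 0.328) / 0.328, 0.005)
  expect_gt(fit$r_squared, 0.9999)
  expect_true(fit$converged)
  expect_equal(fit$K_PF, partition_from_alpha(coef(fit)[["alpha"]], sys))
})

test_that("plateau-fixed mode pins alpha to the last observation", {
  sys <- contact_system()
  # nearly equilibrated curve so the plateau estimate is meaningful
  d <- model_curve(9e-10, 1.5, times = c(1, 2, 4, 8, 24, 48, 72))
  fit <- fit_migration(mr_percent ~ time_h, d, sys,
                       mode = "fix_alpha_from_plateau")
  mr_last <- d$mr_percent[nrow(d)]
  expect_equal(coef(fit)[["alpha"]], mr_last / (100 - mr_last),
               tolerance = 1e-6)
  expect_lt(abs(coef(fit)[["D"]] - 9e-10) / 9e-10, 0.05)
})

test_that("fit methods are mutually consistent", {
  sys <- contact_system()
  d <- model_curve(5e-11, 1.2)
  fit <- fit_migration(mr_percent ~ time_h, d, sys)
  expect_equal(fitted(fit) + residuals(fit), d$mr_percent)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, data.frame(time_h = 72)),
               as.numeric(migration_profile(72, coef(fit)[["D"]],
                                            coef(fit)[["alpha"]])),
               tolerance = 1e-8)
  s <- summary(fit)
  expect_equal(s$plateau_percent,
               100 * equilibrium_fraction(coef(fit)[["alpha"]]))
  sim <- simulate(fit, nsim = 3, seed = 7)
  sim2 <- simulate(fit, nsim = 3, seed = 7)
  expect_identical(sim, sim2)
  expect_equal(dim(sim), c(nrow(d), 3))
})

test_that("degenerate inputs are rejected", {
  sys <- contact_system()
  expect_error(fit_migration(mr_percent ~ time_h,
                             data.frame(time_h = 1:3, mr_percent = 1:3), sys),
               "4 distinct time points")
  expect_error(fit_migration(mr_percent ~ time_h,
                             data.frame(time_h = default_times(),
                                        mr_percent = 0), sys),
               "degenerate")
})

test_that("replicate noise leaves the diffusion estimate close to truth", {
  set.seed(42)
  sys <- contact_system()
  errs <- replicate(10, {
    d <- generate_migration_dataset(
      data.frame(compound = "TPhP", food = "Eastern leaf",
                 alpha = 0.328, D_cm2_s = 8e-11),
      cv = 0.05, n_replicates = 3)
    fit <- fit_migration(mr_percent ~ time_h, d, sys)
    abs(coef(fit)[["D"]] - 8e-11) / 8e-11
  })
  expect_lt(median(errs), 0.15)
})

test_that("the tabular fitter reports one converged record per pair", {
  sys <- contact_system()
  truth <- migration_truth()
  truth <- truth[truth$food == "Eastern leaf" &
                   truth$compound %in% c("TPhP", "TPPO"), ]
  d <- generate_migration_dataset(truth, cv = 0, n_replicates = 1)
  rep <- fit_migration_table(d, sys)
  expect_equal(nrow(rep), 2)
  expect_named(rep, c("compound", "food", "alpha", "K_PF", "D_cm2_s",
                      "r_squared", "n_terms", "converged"))
  expect_true(all(rep$converged))
  expect_true(all(rep$r_squared > 0.9999))
  expect_rel(rep$D_cm2_s, truth$D_cm2_s[match(rep$compound, truth$compound)],
             0.005)
  expect_error(fit_migration_table(d[0, ], sys), "empty")
})
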