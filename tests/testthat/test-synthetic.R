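test_that("noiseless generation equals the analytic model", {
  truth <- migration_truth()[1:2, ]
  d <- generate_migration_dataset(truth, cv = 0, n_replicates = 2)
  for (i in 1:2) {
    sub <- d[d$compound == truth$compound[i] & d$replicate == 1, ]
    expect_equal(sub$mr_percent,
                 as.numeric(migration_profile(sub$time_h, truth$D_cm2_s[i],
                                              truth$alpha[i])))
  }
})

test_that("generation is bit-identical under a fixed seed", {
  truth <- migration_truth()[seq(1, 45, by = 9), ]
  d1 <- generate_migration_dataset(truth, seed = 123)
  d2 <- generate_migration_dataset(truth, seed = 123)
  expect_identical(d1, d2)
  d3 <- generate_migration_dataset(truth, seed = 124)
  expect_false(identical(d1, d3))
  g1 <- generate_digestion_dataset(seed = 5)
  g2 <- generate_digestion_dataset(seed = 5)
  expect_identical(g1, g2)
})

test_that("reference pair approaches its equilibrium plateau by 72 h", {
  truth <- migration_truth()
  row <- truth[truth$food == "Eastern leaf" & truth$compound == "TPhP", ]
  d <- generate_migration_dataset(row, cv = 0, n_replicates = 1)
  plateau <- 100 * equilibrium_fraction(row$alpha)  # 24.7 %
  expect_equal(plateau, 24.7, tolerance = 1e-3)
  expect_lt(abs(d$mr_percent[d$time_h == 72] - plateau), 2)
})

test_that("missing ground truth is a configuration error", {
  truth <- migration_truth()[1:2, ]
  truth$D_cm2_s[2] <- NA
  expect_error(generate_migration_dataset(truth), "incomplete")
  expect_error(generate_migration_dataset(truth[, 1:3]), "lacks columns")
})

test_that("noise-free digestion data recover the true bioaccessibility exactly", {
  dig <- generate_digestion_dataset(cv = 0, blanks = NULL)
  summ <- summarize_ba(ba_from_digestion(dig$samples, dig$blanks))
  expect_equal(summ$ba_percent, unname(ba_truth()[summ$compound]))
  expect_true(all(summ$ba_sd == 0))
})

test_that("blank correction inverts the added contamination", {
  clean <- generate_digestion_dataset(cv = 0, blanks = NULL, seed = 1)
  contaminated <- generate_digestion_dataset(cv = 0, seed = 1)
  # contaminated measurements are higher for the affected compounds
  bl <- contaminated$blanks
  aff <- contaminated$samples$compound %in% bl$compound[bl$blank_ng_ml > 0]
  expect_true(all(contaminated$samples$C_d_ng_ml[aff] >
                    clean$samples$C_d_ng_ml[aff]))
  corrected <- ba_from_digestion(contaminated$samples, contaminated$blanks)
  expect_equal(summarize_ba(corrected)$ba_percent,
               summarize_ba(ba_from_digestion(clean$samples))$ba_percent)
})

test_that("seeded noisy digestion run recovers the truth within 3 points", {
  dig <- generate_digestion_dataset(cv = 0.05, n_replicates = 3, seed = 21)
  summ <- summarize_ba(ba_from_digestion(dig$samples, dig$blanks))
  means <- tapply(summ$ba_percent, summ$compound, mean)
  expect_lt(max(abs(means - ba_truth()[names(means)])), 3)
})
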