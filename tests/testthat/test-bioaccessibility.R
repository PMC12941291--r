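test_that("blank correction subtracts background and floors at zero", {
  expect_equal(as.numeric(blank_correct(50.0, 1.30)), 48.7)
  floored <- blank_correct(0.5, 1.30)
  expect_equal(as.numeric(floored), 0)
  expect_true(attr(floored, "floored"))
  expect_equal(as.numeric(blank_correct(7.5, 0)), 7.5)
  # never increases a concentration
  x <- c(0, 0.3, 1.5, 40)
  expect_true(all(as.numeric(blank_correct(x, 1.2)) <= x))
  expect_error(blank_correct(-1, 0), "non-negative")
})

test_that("bioaccessibility is the recovered-amount over spiked-amount ratio", {
  expect_equal(compute_ba(C_d = 12.5, V_d = 40, C_s = 100, V_s = 5), 100)
  expect_equal(compute_ba(0, 40, 100, 5), 0)
  expect_equal(compute_ba(C_d = 100 / 8, V_d = 4 * 5, C_s = 100, V_s = 5), 50)
  expect_error(compute_ba(1, 40, 0, 5), "C_s")
  expect_error(compute_ba(1, 40, 100, 0), "V_s")
  expect_warning(compute_ba(20, 40, 100, 5), "exceed 100")
})

test_that("bioaccessibility is invariant under common rescaling", {
  base <- compute_ba(5, 40, 100, 5)
  for (k in c(0.1, 2, 7)) {
    expect_equal(compute_ba(5 * k, 40, 100 * k, 5), base)
    expect_equal(compute_ba(5, 40 * k, 100, 5 * k), base)
  }
})

test_that("summaries report mean, sample sd and n per group", {
  s <- summarize_ba(c(50, 50, 50))
  expect_equal(s$ba_percent, 50)
  expect_equal(s$ba_sd, 0)
  s2 <- summarize_ba(c(40, 50, 60))
  expect_equal(s2$ba_percent, 50)
  expect_equal(s2$ba_sd, 10)
  expect_equal(s2$n, 3L)
  expect_error(summarize_ba(numeric(0)), "empty")
})

test_that("blank correction commutes with the bioaccessibility arithmetic", {
  dig <- generate_digestion_dataset(cv = 0.04, seed = 11)
  a <- ba_from_digestion(dig$samples, dig$blanks)
  manual <- as.numeric(blank_correct(
    dig$samples$C_d_ng_ml,
    dig$blanks$blank_ng_ml[match(dig$samples$compound,
                                 dig$blanks$compound)]))
  expect_equal(a$ba_percent,
               suppressWarnings(compute_ba(manual, dig$samples$V_d_ml,
                                           dig$samples$C_s_ng_ml,
                                           dig$samples$V_s_ml)))
})

test_that("unknown compounds in a blank batch fall back to zero with a warning", {
  samples <- data.frame(compound = "X", food = "f", replicate = 1,
                        C_d_ng_ml = 10, V_d_ml = 40, C_s_ng_ml = 100,
                        V_s_ml = 5, blank_batch = "B1")
  blanks <- data.frame(batch = "B1", compound = "Y", blank_ng_ml = 1)
  expect_warning(out <- ba_from_digestion(samples, blanks), "treated as blank 0")
  expect_equal(out$C_d_corrected, 10)
})

test_that("recovered compound ordering matches the generating truth", {
  dig <- generate_digestion_dataset(cv = 0.05, seed = 3)
  summ <- summarize_ba(ba_from_digestion(dig$samples, dig$blanks))
  means <- tapply(summ$ba_percent, summ$compound, mean)
  expect_equal(names(sort(means, decreasing = TRUE)),
               c("TPPO", "TBOEP", "TnBP", "TPhP", "EHDPP"))
})
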