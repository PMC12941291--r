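test_that("intake arithmetic is linear in consumption and concentration", {
  expect_equal(edi_concentration(0, 500), 0)
  expect_equal(edi_concentration(1, 60, 60), 1)
  expect_equal(edi_concentration(2, 60, 60), 2 * edi_concentration(1, 60, 60))
  expect_error(edi_concentration(1, 60, 0), "positive")
})

test_that("migration-based EDI matches the closed form and reduces to Eq.-7 form", {
  expect_equal(edi_from_migration(V = 0.6, mr_f = 50, ba = 100), 2000)
  expect_equal(edi_from_migration(0.6, 0, 50), 0)
  expect_equal(edi_from_migration(0.6, 50, 0), 0)
  # bilinear in MR and BA
  base <- edi_from_migration(0.6, 20, 40)
  expect_equal(edi_from_migration(0.6, 60, 40), 3 * base)
  expect_equal(edi_from_migration(0.6, 20, 80), 2 * base)
  # with BA = 100 it equals the plain concentration form
  C <- 100 * (37 / 100) * 4 * 1e3
  expect_equal(edi_from_migration(0.25, 37, 100), edi_concentration(0.25, C))
})

test_that("hazard quotients reproduce the published anchor rows", {
  expect_equal(hazard_quotient(905.78, 15000), 6.04e-2, tolerance = 1e-3)
  expect_equal(hazard_quotient(1278.44, 20000), 6.39e-2, tolerance = 1e-3)
  expect_equal(hazard_quotient(15000, 15000), 1)
  expect_error(hazard_quotient(1, 0), "positive")
})

test_that("risk assessment joins, classifies, and names missing compounds", {
  d <- data.frame(compound = c("TBOEP", "TPPO"), food = "Eastern leaf",
                  scenario = "median", V_kg_day = 0.5,
                  mr_f_percent = c(30, 60), ba_percent = c(75, 85))
  out <- assess_exposure(d)
  expect_equal(out$edi,
               0.5 * 100 * c(0.30, 0.60) * 4 * 1e3 / 60 * c(0.75, 0.85))
  expect_equal(out$hq, out$edi / c(15000, 20000))
  expect_true(all(out$acceptable))
  d$compound <- c("TBOEP", "Unknown")
  expect_error(assess_exposure(d), "Unknown")
})

test_that("the HQ = 1 boundary is classified as not acceptable", {
  d <- data.frame(compound = "TBOEP", food = "f", scenario = "median",
                  V_kg_day = 1, mr_f_percent = 100, ba_percent = 100)
  # V * C_p * m_p * 1e3 / BW = 1*100*4*1000/60 = 6666.7 -> scale V for HQ = 1
  d$V_kg_day <- 15000 * 60 / (100 * 4 * 1e3)
  out <- assess_exposure(d)
  expect_equal(out$hq, 1)
  expect_false(out$acceptable)
})

test_that("risk summary finds per-compound maxima and flags exceedances", {
  edi <- load_fixture("edi_table3")
  rfd <- rfd_registry()
  res <- data.frame(compound = edi$compound, food = edi$food,
                    scenario = edi$scenario, edi = edi$edi_ng_kg_bw_day,
                    hq = hazard_quotient(edi$edi_ng_kg_bw_day,
                                         rfd[edi$compound]))
  rs <- risk_summary(res)
  expect_equal(nrow(rs$flagged), 0)   # all published HQ below one
  mh <- rs$max_hq
  expect_equal(mh$hq[mh$compound == "TBOEP"], 1.51e-1, tolerance = 3e-3)
  expect_equal(mh$hq[mh$compound == "TPPO"], 1.78e-1, tolerance = 3e-3)
  # single row is its own maximum
  one <- risk_summary(res[5, ])
  expect_equal(one$max_hq$hq, res$hq[5])
  # a synthetic exceedance is flagged
  res2 <- rbind(res, data.frame(compound = "TBOEP", food = "f",
                                scenario = "median", edi = 2e4, hq = 2e4 / 15000))
  expect_equal(nrow(risk_summary(res2)$flagged), 1)
})

test_that("EDI ranking within a food is invariant to the common consumption", {
  d <- data.frame(compound = c("TPhP", "TBOEP", "TPPO"), food = "f",
                  scenario = "median", V_kg_day = 0.3,
                  mr_f_percent = c(20, 55, 70), ba_percent = c(50, 75, 85))
  r1 <- order(-assess_exposure(d)$edi)
  d$V_kg_day <- 1.7
  expect_equal(order(-assess_exposure(d)$edi), r1)
})
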