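test_that("geometric projection matches a year-by-year compounding loop", {
  expect_equal(project_population(5e6, 0, 9), 5e6) # zero growth is identity
  expect_equal(project_population(1000, 3, 1), 1030)
  set.seed(11)
  for (i in 1:20) {
    pop <- runif(1, 1e4, 1e7)
    g <- runif(1, 0, 6)
    n <- sample(0:25, 1)
    expect_equal(project_population(pop, g, n), oracle_compound(pop, g, n))
  }
})

test_that("projection is monotone and back-division recovers the census", {
  base <- project_population(3934899, 3.2, 9)
  expect_gt(project_population(3934899, 3.3, 9), base)
  expect_gt(project_population(3934899, 3.2, 10), base)
  # round trip within 1 person
  expect_equal(base / (1 + 3.2 / 100)^9, 3934899, tolerance = 1 / 3934899)
  expect_error(project_population(-5, 3, 2), class = "mchfundr_invalid_input")
  expect_error(project_population(100, 3, -1), class = "mchfundr_invalid_input")
})

test_that("target derivation reproduces the published beneficiary counts", {
  tg <- derive_targets(7976740)
  expect_equal(tg$pregnant_women, 398837)
  expect_equal(tg$under_five, 1595348) # exact 0.20 x 7,976,740
  expect_equal(tg$all_mch, tg$pregnant_women + tg$under_five)

  # zero fractions give zero targets
  z <- derive_targets(1e6, demography_params(pregnant_fraction = 0,
                                             under5_fraction = 0))
  expect_equal(unlist(z), c(pregnant_women = 0, under_five = 0, all_mch = 0))

  # homogeneity before rounding: doubling the population doubles the
  # unrounded counts (so the rounded counts agree within rounding)
  p <- 123456.25
  tg2 <- derive_targets(2 * p)
  expect_equal(tg2$pregnant_women, round_half_up(2 * 0.05 * p))
  expect_equal(tg2$under_five, round_half_up(2 * 0.20 * p))
  expect_error(derive_targets(0), class = "mchfundr_invalid_input")
})

test_that("vulnerable subsetting scales and rounds half-up", {
  fx <- reference_fixtures()$targets
  v <- vulnerable_subset(fx, 0.63)
  # 0.63 x 1,994,184 = 1,256,335.92 and 0.63 x 1,306,143 = 822,870.09
  expect_equal(v$all_mch[fx$state == "Kaduna"], 1256336)
  expect_equal(v$all_mch[fx$state == "Imo"], 822870)
  expect_identical(vulnerable_subset(fx, 1)$all_mch, fx$all_mch) # identity
  for (f in c(0, 0.3, 0.61, 0.99)) {
    expect_true(all(vulnerable_subset(fx, f)$all_mch <= fx$all_mch))
  }
  expect_error(vulnerable_subset(fx, 1.2), class = "mchfundr_invalid_input")
})

test_that("the study-state pipeline reproduces published targets", {
  tg <- project_targets(study_state_profiles())
  fx <- reference_fixtures()$targets
  expect_equal(tg$pregnant_women, fx$pregnant_women)
  expect_equal(tg$under_five, fx$under_five)
  # the published Imo ALL-MCH total mis-sums its own parts by 1
  expect_true(all(abs(tg$all_mch - fx$all_mch) <= 1))
  expect_equal(tg$all_mch, tg$pregnant_women + tg$under_five)
  expect_true(all(abs(tg$all_mch_vulnerable - fx$all_mch_vulnerable) <= 1))
})

test_that("state profiles round-trip through CSV with schema validation", {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(study_state_profiles(), path)
  prof <- read_state_profiles(path)
  expect_equal(prof$census_population,
               study_state_profiles()$census_population)
  readr::write_csv(dplyr::select(study_state_profiles(), -growth_rate), path)
  expect_error(read_state_profiles(path), class = "mchfundr_config_error")
})
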