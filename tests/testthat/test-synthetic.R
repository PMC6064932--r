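test_that("noiseless generation recovers target unit costs exactly", {
  cfg <- synthetic_config(seed = 3, n_facilities = 4, noise_cv = 0)
  st <- cost_state(generate_facility_ledgers(cfg), 255)
  expect_equal(st$unit_capital, 43.9)
  expect_equal(st$unit_personnel, 676.5)
  expect_equal(st$unit_overhead, 9.7)
})

test_that("generation is deterministic for a fixed seed and leaves the RNG alone", {
  cfg <- synthetic_config(seed = 42, n_facilities = 5, noise_cv = 0.1)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  a <- generate_facility_ledgers(cfg)
  after <- runif(1) # generator must restore the caller's RNG state
  b <- generate_facility_ledgers(cfg)
  expect_identical(a, b)
  expect_identical(before, after)
  c2 <- generate_facility_ledgers(synthetic_config(seed = 43,
                                                   n_facilities = 5,
                                                   noise_cv = 0.1))
  expect_false(identical(a, c2))
})

test_that("noisy generation recovers targets within 3% at 50 facilities", {
  cfg <- synthetic_config(seed = 42, n_facilities = 50, noise_cv = 0.1)
  ledgers <- generate_facility_ledgers(cfg)
  st <- cost_state(ledgers, 255)
  expect_equal(st$unit_capital, 43.9, tolerance = 0.03)
  expect_equal(st$unit_personnel, 676.5, tolerance = 0.03)
  expect_equal(st$unit_overhead, 9.7, tolerance = 0.03)
  # independent spreadsheet-style re-aggregation of the emitted ledgers
  ora <- oracle_aggregate_ledgers(ledgers, 0.03)
  expect_equal(st$unit_capital, ora$unit_capital)
  expect_equal(st$unit_personnel, ora$unit_personnel)
  expect_equal(st$unit_overhead, ora$unit_overhead)
})

test_that("state bundles close the loop on published package unit costs", {
  kd <- generate_state_bundle("Kaduna", seed = 7)
  est <- estimate_from_ledgers(kd$ledgers, 255)
  expect_equal(est$maternal_package, 4774, tolerance = 0.01)
  expect_equal(est$state_costs$unit_capital, 43.9, tolerance = 0.03)
  im <- generate_state_bundle("Imo", seed = 7)
  est_im <- estimate_from_ledgers(im$ledgers, 418)
  expect_equal(est_im$child_package, 385, tolerance = 0.01)
  ng <- generate_state_bundle("Niger", seed = 1, n_facilities = 2)
  expect_equal(ng$profile$mch_weight, 0.9)
})

test_that("bundles write the same delimited schemas the costing module reads", {
  dir <- file.path(tempdir(), "bundle-out")
  generate_state_bundle("Kaduna", seed = 2, n_facilities = 2, dir = dir)
  expect_true(file.exists(file.path(dir, "state_profile.csv")))
  expect_true(file.exists(file.path(dir, "price_list.csv")))
  pl <- read_price_list(file.path(dir, "price_list.csv"))
  expect_equal(nrow(pl), 12)
  lg <- read_facility_ledger(file.path(dir, "fac001"))
  expect_s3_class(lg, "facility_ledger")
  unlink(dir, recursive = TRUE)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(maternal_visit_mean = 0,
                                child_visit_mean = 0),
               class = "mchfundr_config_error")
  expect_error(synthetic_config(noise_cv = -0.1),
               class = "mchfundr_invalid_input")
})

test_that("reference fixtures are byte-stable and carry the published scalars", {
  fx <- reference_fixtures()
  pl <- fx$price_list
  expect_equal(pl$naira_cost[pl$service == "antenatal_care"], 2837.6)
  expect_equal(fx$revenue$nhis_state_share, 521013514)
  expect_equal(length(unique(fx$scenario1_tables$scenario_id)), 4)
  expect_equal(nrow(fx$scenario1_tables), 48)
  # frozen checksum over every transcribed number
  expect_identical(fixture_checksum(), FIXTURE_CHECKSUM)
})
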