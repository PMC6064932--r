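test_that("capital annualization agrees with a bisection oracle and its limits", {
  expect_equal(annualize_capital(100000, 5, 0), 20000)  # straight-line limit
  expect_equal(annualize_capital(100000, 1, 0), 100000)
  for (case in list(c(100000, 5, 0.03), c(250000, 30, 0.03),
                    c(80000, 10, 0.07))) {
    expect_equal(annualize_capital(case[1], case[2], case[3]),
                 oracle_annuity_payment(case[1], case[2], case[3]),
                 tolerance = 1e-7)
  }
  # annuity factor tends to the straight-line value as r -> 0
  expect_equal(annualize_capital(100000, 5, 1e-9), 20000, tolerance = 1e-6)
  expect_error(annualize_capital(100, 5, -0.01),
               class = "mchfundr_invalid_input")
})

test_that("utilization weighting and unit-cost primitives behave", {
  expect_equal(compute_mch_weight(83, 100), 0.83)
  expect_equal(compute_mch_weight(9, 10), 0.9)
  expect_equal(compute_mch_weight(0, 100), 0)
  expect_error(compute_mch_weight(5, 0), class = "mchfundr_degenerate_input")
  expect_error(compute_mch_weight(11, 10), class = "mchfundr_invalid_input")

  expect_equal(allocate_to_mch(1e6, 1), 1e6)
  expect_equal(allocate_to_mch(1e6, 0), 0)
  expect_error(allocate_to_mch(1e6, 1.1), class = "mchfundr_invalid_input")

  expect_equal(unit_component_cost(100, 100), 1)
  expect_equal(unit_component_cost(0, 50), 0)
  expect_error(unit_component_cost(10, 0), class = "mchfundr_degenerate_input")

  expect_equal(scale_to_state(123.4, 0), 0)
  expect_equal(scale_to_state(123.4, 1), 123.4)
  # weight-then-scale equals scale-then-weight
  expect_equal(scale_to_state(allocate_to_mch(1088497.9, 0.83), 418),
               allocate_to_mch(scale_to_state(1088497.9, 418), 0.83))

  expect_equal(to_usd(305.5, 305.5), 1)
  expect_equal(to_usd(0), 0)
  expect_equal(round_half_up(to_usd(2837.6), 1), 9.3)
  expect_error(to_usd(10, 0), class = "mchfundr_invalid_input")
})

test_that("maternal package cost assembles core, optional and per-visit parts", {
  pl <- study_price_list()
  # full family-planning weight, no complications: sum of printed prices
  expect_equal(maternal_package_cost(pl, c(family_planning = 1)),
               2837.6 + 1503.2 + 339.8 + 365.7)
  zero <- dplyr::mutate(pl, naira_cost = 0)
  expect_equal(maternal_package_cost(zero, c(family_planning = 1)), 0)
  # per-visit components accrue over anc_visits + delivery + PNC = 6 visits
  expect_equal(maternal_package_cost(pl, numeric(), per_visit_components = 10),
               2837.6 + 1503.2 + 339.8 + 60)
  # ANC charged per visit under the alternative pricing convention
  pv <- costing_params(anc_drug_pricing = "per_visit")
  expect_equal(maternal_package_cost(pl, numeric(), pv),
               4 * 2837.6 + 1503.2 + 339.8)
  expect_error(maternal_package_cost(pl, c(child_malaria = 1)),
               class = "mchfundr_config_error")
  expect_error(maternal_package_cost(pl[-1, ], numeric()),
               class = "mchfundr_config_error")
})

test_that("child package cost is visits times the mix-weighted price", {
  pl <- study_price_list()
  expect_equal(child_package_cost(pl, c(child_malaria = 1)), 3 * 472.4)
  zero <- dplyr::mutate(pl, naira_cost = 0)
  expect_equal(child_package_cost(zero, c(child_malaria = 0.5,
                                          measles = 0.5)), 0)
  expect_error(child_package_cost(pl, c(child_malaria = 0.5)),
               class = "mchfundr_config_error") # mix must sum to 1
  expect_error(child_package_cost(pl, c(antenatal_care = 1)),
               class = "mchfundr_config_error")
  # linear in prices: doubling every price doubles the cost
  mix <- state_service_mixes("Niger")$child
  expect_equal(child_package_cost(dplyr::mutate(pl, naira_cost = 2 * naira_cost),
                                  mix),
               2 * child_package_cost(pl, mix))
})

test_that("combined unit cost reproduces published values and stays bracketed", {
  expect_equal(combined_unit_cost(4774, 344), 1230)
  expect_equal(combined_unit_cost(0, 0), 0)
  # unrounded Niger cells: displays 1,627
  cmb <- combined_unit_cost(4758.96, 843.46)
  expect_equal(cmb, 1626.56)
  expect_equal(round_half_up(cmb), 1627)
  set.seed(21)
  for (i in 1:25) {
    m <- runif(1, 0, 1e4); ch <- runif(1, 0, 1e4)
    x <- combined_unit_cost(m, ch)
    expect_gte(x, min(m, ch)); expect_lte(x, max(m, ch))
  }
})

test_that("calibrated mixes reproduce the frozen presets and published unit costs", {
  fx <- reference_fixtures()$package_costs
  pl <- study_price_list()
  for (i in 1:3) {
    st <- fx$state[i]
    preset <- state_service_mixes(st)
    m_cal <- calibrate_maternal_mix(fx$maternal_drugs[i], pl)
    c_cal <- calibrate_child_mix(fx$child_drugs[i], pl)
    expect_equal(m_cal, preset$maternal, tolerance = 1e-10)
    expect_equal(c_cal, preset$child, tolerance = 1e-10)
    # recomputation closes the loop on the published unit costs
    expect_equal(maternal_package_cost(pl, preset$maternal),
                 fx$maternal_drugs[i], tolerance = 1e-9)
    expect_equal(child_package_cost(pl, preset$child),
                 fx$child_drugs[i], tolerance = 1e-9)
    expect_equal(round_half_up(maternal_package_cost(pl, preset$maternal)),
                 fx$maternal_drugs_display[i])
  }
  expect_error(calibrate_maternal_mix(1000, pl),
               class = "mchfundr_config_error") # below the core base
  expect_error(calibrate_child_mix(3 * 10000, pl),
               class = "mchfundr_config_error") # outside the price range
})

test_that("component sets are nested: adding components never lowers cost", {
  mixes <- state_service_mixes("Kaduna")
  cc <- c(capital = 43.9, personnel = 676.5, overhead = 9.7)
  pl <- study_price_list()
  sets <- c("drugs_only", "drugs_overheads", "all_components")
  costs <- purrr::map_dfr(sets, function(s) {
    package_unit_cost(pl, mixes$maternal, mixes$child, cc, s)
  })
  expect_true(all(diff(costs$maternal) > 0))
  expect_true(all(diff(costs$child) > 0))
  expect_true(all(diff(costs$combined) > 0))
  # drugs+overheads adds exactly the overhead per visit
  expect_equal(costs$maternal[2] - costs$maternal[1], 9.7 * 6)
  expect_equal(costs$child[2] - costs$child[1], 9.7 * 3)
})

test_that("facility costing matches independent spreadsheet arithmetic", {
  lg <- facility_ledger(
    facility_id = "f1",
    capital_items = tibble::tibble(
      category = c("building", "medical_equipment"),
      replacement_cost = c(3e6, 500000),
      useful_life = c(30, 5),
      acquisition_year = 2012
    ),
    personnel_annual = 1.2e6,
    overhead_annual = 240000,
    drug_line_items = tibble::tibble(
      service = c("antenatal_care", "child_malaria"),
      quantity = c(120, 800),
      unit_price = c(2837.6, 472.4)
    ),
    visits_total = 10000,
    visits_mch = 9000
  )
  fc <- cost_facility(lg, costing_params())
  ann <- 3e6 * 0.03 / (1 - 1.03^-30) + 5e5 * 0.03 / (1 - 1.03^-5)
  expect_equal(fc$mch_weight, 0.9)
  expect_equal(fc$capital_mch, ann * 0.9)
  expect_equal(fc$unit_personnel, 1.2e6 * 0.9 / 9000)
  expect_equal(fc$drugs_total, 120 * 2837.6 + 800 * 472.4)

  st <- cost_state(list(lg, lg), n_standard_facilities = 274)
  expect_equal(st$capital_total, ann * 0.9 * 274) # mean of two equal ledgers
  expect_equal(st$unit_overhead, 240000 * 0.9 / 9000)
  expect_error(cost_state(list(), 10), class = "mchfundr_degenerate_input")
})

test_that("facility ledgers round-trip through delimited files", {
  bundle <- generate_state_bundle("Niger", seed = 5, n_facilities = 2,
                                  noise_cv = 0.05)
  lg <- bundle$ledgers[[1]]
  dir <- file.path(tempdir(), "ledger-rt")
  write_facility_ledger(lg, dir)
  back <- read_facility_ledger(dir)
  expect_equal(back$capital_items, lg$capital_items)
  expect_equal(back$drug_line_items, lg$drug_line_items)
  expect_equal(back$visits_mch, lg$visits_mch)
  expect_equal(back$maternal_service_mix, lg$maternal_service_mix)
  unlink(dir, recursive = TRUE)
  expect_error(read_facility_ledger(tempdir()),
               class = "mchfundr_config_error")
})
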