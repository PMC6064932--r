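#' Amount required to cover a target group for a year
#'
#' @param unit_cost Per-beneficiary package cost (Naira, unrounded).
#' @param targets Number of target beneficiaries, nonnegative.
#' @return Naira/yr, unrounded.
#' @export
required_amount <- function(unit_cost, targets) {
  check_number(unit_cost, "unit_cost", min = 0)
  check_number(targets, "targets", min = 0)
  unit_cost * targets
}

#' Funding gap or surplus
#'
#' Available revenue minus required amount; negative values signal
#' infeasibility.
#'
#' @param available Available revenue (Naira/yr).
#' @param required Required amount (Naira/yr).
#' @return Signed Naira/yr.
#' @export
funding_gap <- function(available, required) {
  check_number(available, "available")
  check_number(required, "required")
  available - required
}

#' Additional aggregate funds needed, as a percentage of available
#'
#' `-100 * gap / available`: shortfalls give positive percentages,
#' surpluses negative ones. Round half-up to integer for display.
#'
#' @param gap Signed funding gap (Naira/yr).
#' @param available Available revenue, positive.
#' @return Signed percent, unrounded.
#' @examples
#' round_half_up(additional_pct(-739822765, 521013514)) # 142
#' @export
additional_pct <- function(gap, available) {
  check_number(gap, "gap")
  check_number(available, "available")
  if (any(available <= 0)) {
    abort_degenerate("`available` must be positive.")
  }
  -100 * gap / available
}

#' Lives covered by the available revenue
#'
#' Whole beneficiaries fully payable from the available revenue:
#' `floor(available / unit_cost)` with the unit cost taken unrounded.
#'
#' @param available Available revenue (Naira/yr).
#' @param unit_cost Per-beneficiary package cost (Naira), positive and
#'   unrounded.
#' @return Persons (integer-valued).
#' @export
lives_covered <- function(available, unit_cost) {
  check_number(available, "available", min = 0)
  check_number(unit_cost, "unit_cost", min = 0)
  if (any(unit_cost == 0)) {
    abort_degenerate("`unit_cost` must be positive.")
  }
  floor(available / unit_cost)
}

#' Minimum percent of the CRF that covers a required amount
#'
#' Solves for the smallest continuous `x` (in percent-of-CRF units, so
#' `x = 1` is the current statutory 1%) such that a state's share of the
#' scaled fund, at the given allocation fraction, covers `max_required`:
#' `x = max_required * n_sharing_units / (allocation_fraction *
#' crf_one_percent)`.
#'
#' @param max_required Largest state-level required amount (Naira/yr),
#'   positive.
#' @param alloc A [fund_allocation()] object.
#' @param allocation_fraction Fraction of the fund reaching the state
#'   pool (default 0.50, the NHIS component), positive.
#' @return A list with `minimum_percent` (continuous) and
#'   `minimum_percent_ceiling`.
#' @examples
#' minimum_crf_percent(2452757841)
#' @export
minimum_crf_percent <- function(max_required, alloc = fund_allocation(),
                                allocation_fraction = 0.50) {
  check_number(max_required, "max_required", min = 0)
  if (max_required == 0) {
    return(list(minimum_percent = 0, minimum_percent_ceiling = 0))
  }
  stopifnot(inherits(alloc, "fund_allocation"))
  check_proportion(allocation_fraction, "allocation_fraction")
  if (allocation_fraction == 0) {
    abort_degenerate("`allocation_fraction` must be positive.")
  }
  x <- max_required * alloc$n_sharing_units /
    (allocation_fraction * alloc$crf_one_percent)
  list(minimum_percent = x, minimum_percent_ceiling = ceiling(x))
}

#' Unit costs of the benefit package for the study states
#'
#' Per-beneficiary package costs by cost-component set for the three
#' study states, assembled from the built-in reference values: drugs
#' only (unrounded, recovered as required amount over targets), drugs
#' plus overheads (adding the per-visit overhead component over the
#' package visit schedule), and all components (the published totals).
#'
#' @param component_set One of `"drugs_only"`, `"drugs_overheads"`,
#'   `"all_components"`, or `"all"` for every set.
#' @param params A [costing_params()] object (visit schedule and
#'   mother/child probabilities).
#' @return A tibble with columns `state`, `component_set`, `maternal`,
#'   `child`, `combined` (Naira, unrounded).
#' @export
study_unit_costs <- function(component_set = c("all", "drugs_only",
                                               "drugs_overheads",
                                               "all_components"),
                             params = costing_params()) {
  component_set <- match.arg(component_set)
  fx <- reference_fixtures()
  pc <- fx$package_costs
  cu <- fx$component_unit_costs
  m_visits <- params$anc_visits + 2
  c_visits <- params$child_visits_per_year
  sets <- list(
    drugs_only = tibble::tibble(
      state = pc$state, component_set = "drugs_only",
      maternal = pc$maternal_drugs, child = pc$child_drugs),
    drugs_overheads = tibble::tibble(
      state = pc$state, component_set = "drugs_overheads",
      maternal = pc$maternal_drugs + cu$overhead * m_visits,
      child = pc$child_drugs + cu$overhead * c_visits),
    all_components = tibble::tibble(
      state = pc$state, component_set = "all_components",
      maternal = pc$maternal_all_components,
      child = pc$child_all_components)
  )
  out <- if (component_set == "all") dplyr::bind_rows(sets)
         else sets[[component_set]]
  dplyr::mutate(out,
                combined = combined_unit_cost(.data$maternal, .data$child,
                                              params))
}

# Per-group unit cost / target / required conventions, matching the
# published tables:
# - maternal, child: required = group unit cost x group targets.
# - all_mch: required = maternal required + child required; the row's
#   unit cost is the implied required / targets (which rounds to the
#   0.2/0.8-weighted combined unit at display).
# - all_mch_vulnerable: the poverty fraction applied to the ALL-MCH row
#   at its displayed whole-Naira unit cost: required = fraction x
#   round(all-MCH unit) x all-MCH targets, targets = round(fraction x
#   all-MCH targets).
group_row <- function(costs_row, targets_row, group, vulnerable_fraction) {
  m_req <- required_amount(costs_row$maternal, targets_row$pregnant_women)
  c_req <- required_amount(costs_row$child, targets_row$under_five)
  switch(group,
    maternal = list(unit = costs_row$maternal,
                    targets = targets_row$pregnant_women, required = m_req),
    child = list(unit = costs_row$child,
                 targets = targets_row$under_five, required = c_req),
    all_mch = {
      req <- m_req + c_req
      list(unit = req / targets_row$all_mch,
           targets = targets_row$all_mch, required = req)
    },
    all_mch_vulnerable = {
      unit_disp <- round_half_up((m_req + c_req) / targets_row$all_mch)
      req <- vulnerable_fraction * unit_disp * targets_row$all_mch
      tg <- round_half_up(vulnerable_fraction * targets_row$all_mch)
      list(unit = req / tg, targets = tg, required = req)
    },
    abort_config(paste0("Unknown beneficiary group: ", group))
  )
}

#' Run one feasibility scenario for one state and beneficiary group
#'
#' Composes the demography, costing and revenue stages into a single
#' feasibility row: target beneficiaries, per-beneficiary unit cost,
#' required amount, available revenue, lives covered, funding
#' gap/surplus and the additional-funding percentage.
#'
#' @param scenario_id A scenario id known to [scenario_presets()].
#' @param state_profile One-row data frame with at least `state`,
#'   `census_population`, `growth_rate`.
#' @param group One of `"maternal"`, `"child"`, `"all_mch"`,
#'   `"all_mch_vulnerable"`.
#' @param unit_costs Tibble as from [study_unit_costs()] covering the
#'   state and the scenario's component set.
#' @param demog_params A [demography_params()] object.
#' @param params A [costing_params()] object.
#' @param alloc A [fund_allocation()] object.
#' @param revenue_inputs Optional tibble keyed by `state` with columns
#'   `state_phc_budget`, `lga_phc_budget_scaled`, `igr_scaled`.
#' @return A one-row tibble (a feasibility row).
#' @examples
#' run_scenario("1a", study_state_profiles()[2, ], "all_mch")
#' @export
run_scenario <- function(scenario_id, state_profile, group,
                         unit_costs = study_unit_costs(),
                         demog_params = demography_params(),
                         params = costing_params(),
                         alloc = fund_allocation(),
                         revenue_inputs = NULL) {
  spec <- scenario_presets(scenario_id)
  state_profile <- tibble::as_tibble(state_profile)
  if (nrow(state_profile) != 1) {
    abort_config("`state_profile` must be a single row.")
  }
  tg <- project_targets(state_profile, demog_params)
  costs <- dplyr::filter(tibble::as_tibble(unit_costs),
                         .data$state == state_profile$state,
                         .data$component_set == spec$component_set)
  if (nrow(costs) != 1) {
    abort_config(paste0("Missing unit costs for state ", state_profile$state,
                        ", component set ", spec$component_set, "."))
  }
  si <- NULL
  if (!is.null(revenue_inputs)) {
    si <- dplyr::filter(tibble::as_tibble(revenue_inputs),
                        .data$state == state_profile$state)
    if (nrow(si) == 0) si <- NULL
  }
  gr <- group_row(costs, tg, group, demog_params$vulnerable_fraction)
  unit <- gr$unit
  n_targets <- gr$targets
  req <- gr$required
  avail <- scenario_revenue(spec, alloc, si)
  gap <- funding_gap(avail, req)
  tibble::tibble(
    state = state_profile$state,
    group = group,
    scenario_id = scenario_id,
    component_set = spec$component_set,
    unit_cost = unit,
    unit_cost_usd = to_usd(unit, params$exchange_rate),
    targets = n_targets,
    required = req,
    available = avail,
    lives_covered = lives_covered(avail, unit),
    gap = gap,
    additional_pct = additional_pct(gap, avail)
  )
}

#' Coverage and funding-gap analysis across states, groups and scenarios
#'
#' The package's main verb: runs [run_scenario()] over the full grid and
#' returns a classed result with [tidy()], [glance()], `autoplot()` and
#' `print()` methods.
#'
#' @param states State profiles tibble (default the three study states).
#' @param scenario_ids Scenario ids (default the four published
#'   Scenario-1 tables: 1a, 1c, 1d, 1f).
#' @param groups Beneficiary groups to analyze.
#' @inheritParams run_scenario
#' @return An object of class `mch_feasibility` wrapping the rows tibble
#'   and the inputs.
#' @examples
#' fit <- run_feasibility()
#' dplyr::glimpse(tidy(fit))
#' @export
run_feasibility <- function(states = study_state_profiles(),
                            scenario_ids = c("1a", "1c", "1d", "1f"),
                            groups = c("maternal", "child", "all_mch",
                                       "all_mch_vulnerable"),
                            unit_costs = study_unit_costs(),
                            demog_params = demography_params(),
                            params = costing_params(),
                            alloc = fund_allocation(),
                            revenue_inputs = NULL) {
  states <- tibble::as_tibble(states)
  if (!nrow(states)) abort_config("`states` must be nonempty.")
  grid <- tidyr::crossing(scenario_id = scenario_ids,
                          state = states$state,
                          group = groups)
  rows <- purrr::pmap_dfr(grid, function(scenario_id, state, group) {
    run_scenario(scenario_id, states[states$state == state, ], group,
                 unit_costs, demog_params, params, alloc, revenue_inputs)
  })
  rows <- dplyr::arrange(rows, .data$scenario_id,
                         factor(.data$group, levels = groups),
                         .data$state)
  structure(
    list(rows = rows, states = states, scenario_ids = scenario_ids,
         groups = groups, demog_params = demog_params, params = params,
         alloc = alloc),
    class = "mch_feasibility"
  )
}

#' @export
print.mch_feasibility <- function(x, ...) {
  cat("<mch_feasibility>\n")
  cat("  states:    ", paste(x$states$state, collapse = ", "), "\n")
  cat("  scenarios: ", paste(x$scenario_ids, collapse = ", "), "\n")
  cat("  rows:      ", nrow(x$rows), "\n")
  short <- nrow(dplyr::filter(x$rows, .data$gap < 0))
  cat("  rows in shortfall:", short, "of", nrow(x$rows), "\n")
  invisible(x)
}
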