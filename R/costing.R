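#' Canonical benefit-package service names
#'
#' The maternal package covers antenatal care (ANC), facility delivery,
#' postnatal care (PNC) and family planning, plus three pregnancy
#' complications entering by utilization weight; the child package covers
#' curative care for malaria, pneumonia and diarrhea plus routine
#' immunization and measles.
#'
#' @return A list with character vectors `maternal_core`,
#'   `maternal_optional`, `child`.
#' @export
package_services <- function() {
  list(
    maternal_core = c("antenatal_care", "normal_delivery", "postnatal_care"),
    maternal_optional = c("family_planning", "malaria_in_pregnancy",
                          "hypertension_in_pregnancy", "postpartum_hemorrhage"),
    child = c("child_malaria", "pneumonia", "diarrhea",
              "routine_immunization", "measles")
  )
}

price_lookup <- function(prices, services) {
  if (is.data.frame(prices)) {
    if (!all(c("service", "naira_cost") %in% names(prices))) {
      abort_config("`prices` must have columns `service` and `naira_cost`.")
    }
    prices <- stats::setNames(prices$naira_cost, prices$service)
  }
  known <- unlist(package_services(), use.names = FALSE)
  unknown <- setdiff(names(prices), known)
  if (length(unknown)) {
    abort_config(paste0("Unknown service(s) in price list: ",
                        paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(services, names(prices))
  if (length(missing)) {
    abort_config(paste0("Price list is missing service(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(prices < 0)) {
    rlang::abort("Prices must be nonnegative.",
                 class = "mchfundr_invalid_input")
  }
  prices[services]
}

#' Annualize a capital item with the annuity factor
#'
#' Converts a replacement cost into an equivalent annual cost over the
#' item's useful life: `cost * r / (1 - (1 + r)^-L)` at discount rate
#' `r > 0`, with the straight-line `cost / L` as the `r = 0` limit.
#'
#' @param replacement_cost Replacement cost in Naira, nonnegative.
#' @param useful_life Useful life in years, at least 1. Vectorized.
#' @param discount_rate Annual discount rate, nonnegative (default 0.03).
#' @return Equivalent annual cost in Naira/yr.
#' @examples
#' annualize_capital(100000, 5, 0)     # 20,000 straight-line
#' annualize_capital(100000, 5, 0.03)  # 21,835.46
#' @export
annualize_capital <- function(replacement_cost, useful_life,
                              discount_rate = 0.03) {
  check_number(replacement_cost, "replacement_cost", min = 0)
  check_number(useful_life, "useful_life", min = 1)
  check_number(discount_rate, "discount_rate")
  if (any(discount_rate < 0)) {
    rlang::abort("`discount_rate` must be nonnegative.",
                 class = "mchfundr_invalid_input")
  }
  n <- max(length(replacement_cost), length(useful_life),
           length(discount_rate))
  rc <- rep_len(replacement_cost, n)
  L <- rep_len(useful_life, n)
  r <- rep_len(discount_rate, n)
  ifelse(r == 0, rc / L, rc * r / (1 - (1 + r)^(-L)))
}

#' MCH utilization weight of a facility
#'
#' Fraction of all outpatient visits attributable to MCH services, used
#' to allocate shared capital, personnel and overhead costs.
#'
#' @param visits_mch Annual MCH visits.
#' @param visits_total Annual total outpatient visits, positive and at
#'   least `visits_mch`.
#' @return Proportion in \[0, 1\].
#' @examples
#' compute_mch_weight(83, 100) # 0.83
#' @export
compute_mch_weight <- function(visits_mch, visits_total) {
  check_number(visits_mch, "visits_mch", min = 0)
  check_number(visits_total, "visits_total", min = 0)
  if (any(visits_total == 0)) {
    abort_degenerate("`visits_total` must be positive.")
  }
  if (any(visits_mch > visits_total)) {
    rlang::abort("`visits_mch` cannot exceed `visits_total`.",
                 class = "mchfundr_invalid_input")
  }
  visits_mch / visits_total
}

#' Allocate a shared facility cost to MCH services
#'
#' @param total_cost Total annual cost in Naira.
#' @param mch_weight MCH utilization weight in \[0, 1\].
#' @return MCH-attributable cost, `total_cost * mch_weight`.
#' @export
allocate_to_mch <- function(total_cost, mch_weight) {
  check_number(total_cost, "total_cost")
  check_proportion(mch_weight, "mch_weight")
  total_cost * mch_weight
}

#' Per-visit unit cost of a cost component
#'
#' @param mch_cost Annual MCH-attributable cost of the component (Naira).
#' @param mch_visits Annual MCH visits, positive.
#' @return Naira per MCH visit, unrounded.
#' @export
unit_component_cost <- function(mch_cost, mch_visits) {
  check_number(mch_cost, "mch_cost", min = 0)
  check_number(mch_visits, "mch_visits", min = 0)
  if (any(mch_visits == 0)) {
    abort_degenerate("`mch_visits` must be positive.")
  }
  mch_cost / mch_visits
}

#' Scale an average facility cost to the state level
#'
#' State-level cost = average cost per facility times the recommended
#' number of standard PHC facilities in the state (one per ward).
#'
#' @param avg_facility_cost Average annual cost per facility (Naira).
#' @param n_standard_facilities Number of standard PHC facilities.
#' @return State-level annual cost (Naira), unrounded.
#' @export
scale_to_state <- function(avg_facility_cost, n_standard_facilities) {
  check_number(avg_facility_cost, "avg_facility_cost")
  check_number(n_standard_facilities, "n_standard_facilities", min = 0)
  avg_facility_cost * n_standard_facilities
}

#' Convert Naira to US dollars
#'
#' @param amount Naira amount.
#' @param exchange_rate Naira per US$, positive (default 305.5).
#' @return US$ amount, unrounded (display at one decimal).
#' @examples
#' to_usd(2837.6) # 9.288...
#' @export
to_usd <- function(amount, exchange_rate = 305.5) {
  check_number(amount, "amount")
  check_number(exchange_rate, "exchange_rate")
  if (any(exchange_rate <= 0)) {
    rlang::abort("`exchange_rate` must be positive.",
                 class = "mchfundr_invalid_input")
  }
  amount / exchange_rate
}

#' Maternal benefit-package cost per pregnancy
#'
#' Drug-and-consumable part: the ANC course, facility delivery and
#' postnatal care at full weight, plus family planning and the three
#' pregnancy complications weighted by their utilization proportions.
#' Non-drug components (capital, personnel, overheads), when included,
#' accrue per visit across the `anc_visits + 2` visits of the pregnancy
#' episode (ANC visits, delivery, one PNC visit).
#'
#' @param prices Price list: named numeric vector or tibble with columns
#'   `service`, `naira_cost` (see [study_price_list()]).
#' @param mix Named numeric vector of utilization proportions in
#'   \[0, 1\] over the optional maternal services (`family_planning`,
#'   `malaria_in_pregnancy`, `hypertension_in_pregnancy`,
#'   `postpartum_hemorrhage`). Missing services count as 0.
#' @param params A [costing_params()] object.
#' @param per_visit_components Naira per visit of included non-drug
#'   components (0 for a drugs-only package).
#' @return Naira per pregnant woman per year, unrounded.
#' @examples
#' maternal_package_cost(study_price_list(),
#'                       mix = c(family_planning = 1))
#' @export
maternal_package_cost <- function(prices, mix = numeric(),
                                  params = costing_params(),
                                  per_visit_components = 0) {
  stopifnot(inherits(params, "costing_params"))
  sv <- package_services()
  bad <- setdiff(names(mix), sv$maternal_optional)
  if (length(bad)) {
    abort_config(paste0("`mix` may only weight optional maternal services; got: ",
                        paste(bad, collapse = ", ")))
  }
  check_number(per_visit_components, "per_visit_components", min = 0)
  if (length(mix)) check_proportion(unname(mix), "mix")
  w <- stats::setNames(numeric(length(sv$maternal_optional)),
                       sv$maternal_optional)
  w[names(mix)] <- mix
  core <- price_lookup(prices, sv$maternal_core)
  opt <- price_lookup(prices, sv$maternal_optional)
  n_visits <- params$anc_visits + 2
  anc_cost <- if (params$anc_drug_pricing == "per_visit") {
    core[["antenatal_care"]] * params$anc_visits
  } else {
    core[["antenatal_care"]]
  }
  drug <- anc_cost + core[["normal_delivery"]] + core[["postnatal_care"]] +
    sum(opt * w)
  drug + per_visit_components * n_visits
}

#' Child benefit-package cost per child-year
#'
#' `child_visits_per_year` visits, each costing the utilization-weighted
#' mean drug price over the child services, plus any included non-drug
#' components per visit.
#'
#' @inheritParams maternal_package_cost
#' @param mix Named numeric vector of per-visit utilization proportions
#'   over the child services; must sum to 1.
#' @return Naira per under-five child per year, unrounded.
#' @examples
#' child_package_cost(study_price_list(), mix = c(child_malaria = 1))
#' @export
child_package_cost <- function(prices, mix, params = costing_params(),
                               per_visit_components = 0) {
  stopifnot(inherits(params, "costing_params"))
  sv <- package_services()
  bad <- setdiff(names(mix), sv$child)
  if (length(bad)) {
    abort_config(paste0("`mix` may only weight child services; got: ",
                        paste(bad, collapse = ", ")))
  }
  check_proportion(unname(mix), "mix")
  if (abs(sum(mix) - 1) > 1e-8) {
    abort_config("Child service `mix` must sum to 1.")
  }
  check_number(per_visit_components, "per_visit_components", min = 0)
  p <- price_lookup(prices, names(mix))
  params$child_visits_per_year * (sum(p * mix) + per_visit_components)
}

#' Combined per-beneficiary unit cost
#'
#' Expected package cost for a beneficiary who is a mother with
#' probability `p_mother` and an under-five child with probability
#' `p_child`.
#'
#' @param maternal Maternal package cost (Naira/pregnant woman/yr).
#' @param child Child package cost (Naira/child/yr).
#' @param params A [costing_params()] object.
#' @return Naira per beneficiary per year, unrounded; round half-up for
#'   display.
#' @examples
#' combined_unit_cost(4774, 344) # 1230
#' @export
combined_unit_cost <- function(maternal, child, params = costing_params()) {
  stopifnot(inherits(params, "costing_params"))
  check_number(maternal, "maternal", min = 0)
  check_number(child, "child", min = 0)
  params$p_mother * maternal + params$p_child * child
}

#' Package unit costs for a cost-component set
#'
#' Builds the per-beneficiary unit costs of the benefit package for one
#' state-like configuration and a chosen component set: `drugs_only`
#' prices drugs and consumables alone; `drugs_overheads` adds the
#' per-visit overhead component; `all_components` adds capital,
#' personnel and overheads.
#'
#' @param prices Price list (see [maternal_package_cost()]).
#' @param maternal_mix,child_mix Service utilization mixes (see
#'   [maternal_package_cost()] and [child_package_cost()]).
#' @param component_costs Named numeric vector of per-visit unit costs
#'   (Naira/visit) with names among `capital`, `personnel`, `overhead`.
#' @param component_set One of `"drugs_only"`, `"drugs_overheads"`,
#'   `"all_components"`.
#' @param params A [costing_params()] object.
#' @return A one-row tibble: `component_set`, `maternal`, `child`,
#'   `combined` (all Naira, unrounded).
#' @export
package_unit_cost <- function(prices, maternal_mix, child_mix,
                              component_costs = c(capital = 0,
                                                  personnel = 0,
                                                  overhead = 0),
                              component_set = c("drugs_only",
                                                "drugs_overheads",
                                                "all_components"),
                              params = costing_params()) {
  component_set <- match.arg(component_set)
  per_visit <- switch(component_set,
    drugs_only = 0,
    drugs_overheads = component_costs[["overhead"]],
    all_components = sum(component_costs[c("capital", "personnel", "overhead")])
  )
  m <- maternal_package_cost(prices, maternal_mix, params, per_visit)
  ch <- child_package_cost(prices, child_mix, params, per_visit)
  tibble::tibble(component_set = component_set,
                 maternal = m, child = ch,
                 combined = combined_unit_cost(m, ch, params))
}

#' Read a drug-and-consumable price list
#'
#' @param path CSV file with columns `service`, `naira_cost`.
#' @return A validated tibble.
#' @export
read_price_list <- function(path) {
  pl <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("service", "naira_cost") %in% names(pl))) {
    abort_config("Price list file must have columns `service` and `naira_cost`.")
  }
  price_lookup(pl, character()) # validates names and signs
  tibble::as_tibble(pl[c("service", "naira_cost")])
}
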