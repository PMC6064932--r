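#' Construct a facility cost ledger
#'
#' One facility-year of cost and utilization data: the capital
#' inventory, annual personnel and overhead spending, priced drug line
#' items, and the visit register split into total outpatient and MCH
#' visits.
#'
#' @param facility_id Identifier.
#' @param capital_items Tibble with columns `category` (one of
#'   `building`, `transport`, `medical_equipment`, `other`),
#'   `replacement_cost` (Naira), `useful_life` (years),
#'   `acquisition_year`.
#' @param personnel_annual,overhead_annual Annual Naira totals.
#' @param drug_line_items Tibble with columns `service`, `quantity`,
#'   `unit_price` (Naira).
#' @param visits_total,visits_mch Annual visit counts,
#'   `visits_mch <= visits_total`.
#' @param maternal_service_mix,child_service_mix Optional named
#'   utilization mixes (see [maternal_package_cost()],
#'   [child_package_cost()]).
#' @return A list of class `facility_ledger`.
#' @export
facility_ledger <- function(facility_id,
                            capital_items,
                            personnel_annual,
                            overhead_annual,
                            drug_line_items,
                            visits_total,
                            visits_mch,
                            maternal_service_mix = NULL,
                            child_service_mix = NULL) {
  capital_items <- tibble::as_tibble(capital_items)
  need_cap <- c("category", "replacement_cost", "useful_life")
  if (!all(need_cap %in% names(capital_items))) {
    abort_config(paste("`capital_items` must have columns:",
                       paste(need_cap, collapse = ", ")))
  }
  bad <- setdiff(capital_items$category,
                 c("building", "transport", "medical_equipment", "other"))
  if (length(bad)) {
    abort_config(paste0("Unknown capital category: ",
                        paste(unique(bad), collapse = ", ")))
  }
  check_number(capital_items$replacement_cost, "replacement_cost",
               min = 0, allow_zero_len = TRUE)
  if (nrow(capital_items)) {
    check_number(capital_items$useful_life, "useful_life", min = 1)
  }
  check_number(personnel_annual, "personnel_annual", min = 0)
  check_number(overhead_annual, "overhead_annual", min = 0)
  drug_line_items <- tibble::as_tibble(drug_line_items)
  if (!all(c("service", "quantity", "unit_price") %in% names(drug_line_items))) {
    abort_config("`drug_line_items` must have columns service, quantity, unit_price.")
  }
  check_number(visits_total, "visits_total", min = 0)
  check_number(visits_mch, "visits_mch", min = 0)
  if (visits_mch > visits_total) {
    rlang::abort("`visits_mch` cannot exceed `visits_total`.",
                 class = "mchfundr_invalid_input")
  }
  structure(
    list(facility_id = facility_id,
         capital_items = capital_items,
         personnel_annual = personnel_annual,
         overhead_annual = overhead_annual,
         drug_line_items = drug_line_items,
         visits_total = visits_total,
         visits_mch = visits_mch,
         maternal_service_mix = maternal_service_mix,
         child_service_mix = child_service_mix),
    class = "facility_ledger"
  )
}

#' Cost a single facility ledger
#'
#' Annualizes the capital inventory, allocates capital, personnel and
#' overhead totals to MCH by the facility's utilization weight, and
#' divides by MCH visits to give per-visit component unit costs.
#'
#' @param ledger A [facility_ledger()].
#' @param params A [costing_params()] object.
#' @return A one-row tibble: `facility_id`, `mch_weight`, `visits_mch`,
#'   annual MCH-attributable costs `capital_mch`, `personnel_mch`,
#'   `overhead_mch`, `drugs_total`, and per-visit `unit_capital`,
#'   `unit_personnel`, `unit_overhead`.
#' @export
cost_facility <- function(ledger, params = costing_params()) {
  stopifnot(inherits(ledger, "facility_ledger"))
  w <- compute_mch_weight(ledger$visits_mch, ledger$visits_total)
  cap_annual <- if (nrow(ledger$capital_items)) {
    sum(annualize_capital(ledger$capital_items$replacement_cost,
                          ledger$capital_items$useful_life,
                          params$discount_rate))
  } else 0
  cap_mch <- allocate_to_mch(cap_annual, w)
  per_mch <- allocate_to_mch(ledger$personnel_annual, w)
  ovh_mch <- allocate_to_mch(ledger$overhead_annual, w)
  drugs <- sum(ledger$drug_line_items$quantity *
                 ledger$drug_line_items$unit_price)
  tibble::tibble(
    facility_id = ledger$facility_id,
    mch_weight = w,
    visits_mch = ledger$visits_mch,
    capital_mch = cap_mch,
    personnel_mch = per_mch,
    overhead_mch = ovh_mch,
    drugs_total = drugs,
    unit_capital = unit_component_cost(cap_mch, ledger$visits_mch),
    unit_personnel = unit_component_cost(per_mch, ledger$visits_mch),
    unit_overhead = unit_component_cost(ovh_mch, ledger$visits_mch)
  )
}

#' Aggregate facility ledgers to state-level costs
#'
#' Pools the facilities: state component totals scale the average
#' MCH-attributable facility cost by the number of standard PHC
#' facilities; per-visit component unit costs divide pooled MCH costs by
#' pooled MCH visits.
#'
#' @param ledgers A list of [facility_ledger()] objects.
#' @param n_standard_facilities Standard PHC facilities in the state.
#' @param params A [costing_params()] object.
#' @return A one-row tibble with state totals (`capital_total`,
#'   `personnel_total`, `overhead_total`, `drugs_total`), per-visit unit
#'   costs (`unit_capital`, `unit_personnel`, `unit_overhead`), the mean
#'   MCH weight and pooled visit counts.
#' @export
cost_state <- function(ledgers, n_standard_facilities,
                       params = costing_params()) {
  if (!length(ledgers)) abort_degenerate("`ledgers` must be nonempty.")
  per <- purrr::map_dfr(ledgers, cost_facility, params = params)
  visits <- sum(per$visits_mch)
  if (visits == 0) abort_degenerate("No MCH visits across ledgers.")
  tibble::tibble(
    n_facilities_sampled = nrow(per),
    mch_weight = mean(per$mch_weight),
    visits_mch = visits,
    capital_total = scale_to_state(mean(per$capital_mch),
                                   n_standard_facilities),
    personnel_total = scale_to_state(mean(per$personnel_mch),
                                     n_standard_facilities),
    overhead_total = scale_to_state(mean(per$overhead_mch),
                                    n_standard_facilities),
    drugs_total = scale_to_state(mean(per$drugs_total),
                                 n_standard_facilities),
    unit_capital = sum(per$capital_mch) / visits,
    unit_personnel = sum(per$personnel_mch) / visits,
    unit_overhead = sum(per$overhead_mch) / visits
  )
}

# ledger file I/O -----------------------------------------------------------

#' Write a facility ledger as delimited files
#'
#' One directory per facility holding `capital.csv`, `drugs.csv`,
#' `summary.csv` (personnel, overheads, visit register) and, when
#' present, `mix.csv` (service utilization mixes). [read_facility_ledger()]
#' inverts this exactly.
#'
#' @param ledger A [facility_ledger()].
#' @param dir Directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_facility_ledger <- function(ledger, dir) {
  stopifnot(inherits(ledger, "facility_ledger"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(ledger$capital_items, file.path(dir, "capital.csv"))
  readr::write_csv(ledger$drug_line_items, file.path(dir, "drugs.csv"))
  readr::write_csv(
    tibble::tibble(facility_id = ledger$facility_id,
                   personnel_annual = ledger$personnel_annual,
                   overhead_annual = ledger$overhead_annual,
                   visits_total = ledger$visits_total,
                   visits_mch = ledger$visits_mch),
    file.path(dir, "summary.csv")
  )
  mixes <- c(ledger$maternal_service_mix, ledger$child_service_mix)
  if (length(mixes)) {
    readr::write_csv(
      tibble::tibble(service = names(mixes), proportion = unname(mixes),
                     group = rep(c("maternal", "child"),
                                 c(length(ledger$maternal_service_mix),
                                   length(ledger$child_service_mix)))),
      file.path(dir, "mix.csv")
    )
  }
  invisible(dir)
}

#' Read a facility ledger written by [write_facility_ledger()]
#'
#' @param dir Directory holding the ledger files.
#' @return A [facility_ledger()].
#' @export
read_facility_ledger <- function(dir) {
  req <- file.path(dir, c("capital.csv", "drugs.csv", "summary.csv"))
  missing <- req[!file.exists(req)]
  if (length(missing)) {
    abort_config(paste0("Ledger directory is missing file(s): ",
                        paste(basename(missing), collapse = ", ")))
  }
  s <- readr::read_csv(file.path(dir, "summary.csv"), show_col_types = FALSE)
  mix_path <- file.path(dir, "mix.csv")
  m_mix <- c_mix <- NULL
  if (file.exists(mix_path)) {
    mx <- readr::read_csv(mix_path, show_col_types = FALSE)
    m <- mx[mx$group == "maternal", ]
    ch <- mx[mx$group == "child", ]
    if (nrow(m)) m_mix <- stats::setNames(m$proportion, m$service)
    if (nrow(ch)) c_mix <- stats::setNames(ch$proportion, ch$service)
  }
  facility_ledger(
    facility_id = s$facility_id[1],
    capital_items = readr::read_csv(file.path(dir, "capital.csv"),
                                    show_col_types = FALSE),
    personnel_annual = s$personnel_annual[1],
    overhead_annual = s$overhead_annual[1],
    drug_line_items = readr::read_csv(file.path(dir, "drugs.csv"),
                                      show_col_types = FALSE),
    visits_total = s$visits_total[1],
    visits_mch = s$visits_mch[1],
    maternal_service_mix = m_mix,
    child_service_mix = c_mix
  )
}
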