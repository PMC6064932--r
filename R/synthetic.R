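# Synthetic facility registers. The generator emulates the registers the
# costing pipeline consumes — monthly MCH attendance, priced drug
# dispensing, salary/overhead ledgers and a capital inventory — with
# totals constructed so that the pipeline's expected per-component unit
# costs equal configured targets, letting every stage be tested
# end-to-end without any external data.

# mean-preserving multiplicative noise: lognormal with E = 1, CV = cv
jitter_ln <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Configuration for the synthetic facility-register generator
#'
#' @param seed Integer RNG seed; identical configs and seeds give
#'   identical output.
#' @param n_facilities Number of facilities to simulate.
#' @param mch_weight MCH utilization weight of each facility.
#' @param maternal_visit_mean,child_visit_mean Mean annual MCH visits
#'   per facility by group.
#' @param target_unit_costs Named numeric vector (`capital`,
#'   `personnel`, `overhead`): per-visit unit costs (Naira/visit) the
#'   costing pipeline should recover in expectation.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   on volumes, prices and ledger totals (0 = noiseless).
#' @param price_list Price list (see [study_price_list()]).
#' @param maternal_mix,child_mix Service utilization mixes (see
#'   [state_service_mixes()]).
#' @param params A [costing_params()] object.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_facilities = 50,
                             mch_weight = 0.85,
                             maternal_visit_mean = 4690,
                             child_visit_mean = 8671,
                             target_unit_costs = c(capital = 43.9,
                                                   personnel = 676.5,
                                                   overhead = 9.7),
                             noise_cv = 0.1,
                             price_list = study_price_list(),
                             maternal_mix = state_service_mixes("Kaduna")$maternal,
                             child_mix = state_service_mixes("Kaduna")$child,
                             params = costing_params()) {
  check_number(n_facilities, "n_facilities", min = 1)
  check_proportion(mch_weight, "mch_weight")
  check_number(noise_cv, "noise_cv", min = 0)
  check_number(maternal_visit_mean, "maternal_visit_mean", min = 0)
  check_number(child_visit_mean, "child_visit_mean", min = 0)
  stopifnot(all(c("capital", "personnel", "overhead") %in%
                  names(target_unit_costs)))
  check_number(target_unit_costs, "target_unit_costs", min = 0)
  if (maternal_visit_mean + child_visit_mean == 0 &&
      any(target_unit_costs > 0)) {
    abort_config("Zero visit volumes cannot carry nonzero unit-cost targets.")
  }
  structure(
    list(seed = seed, n_facilities = n_facilities, mch_weight = mch_weight,
         maternal_visit_mean = maternal_visit_mean,
         child_visit_mean = child_visit_mean,
         target_unit_costs = target_unit_costs, noise_cv = noise_cv,
         price_list = price_list, maternal_mix = maternal_mix,
         child_mix = child_mix, params = params),
    class = "synthetic_config"
  )
}

generate_one_ledger <- function(config, id) {
  cv <- config$noise_cv
  pp <- config$params
  # monthly attendance by group; annual totals are sums of 12 draws
  m_monthly <- round(config$maternal_visit_mean / 12 * jitter_ln(12, cv))
  c_monthly <- round(config$child_visit_mean / 12 * jitter_ln(12, cv))
  m_visits <- sum(m_monthly)
  c_visits <- sum(c_monthly)
  visits_mch <- m_visits + c_visits
  if (visits_mch == 0) {
    abort_config("Simulated facility has no MCH visits; raise visit means.")
  }
  visits_total <- round(visits_mch / config$mch_weight)

  # drug dispensing priced from the (jittered) price list
  prices <- stats::setNames(config$price_list$naira_cost,
                            config$price_list$service)
  sv <- package_services()
  pregnancies <- m_visits / (pp$anc_visits + 2)
  m_qty <- c(stats::setNames(rep(pregnancies, 3), sv$maternal_core),
             config$maternal_mix[sv$maternal_optional] * pregnancies)
  c_qty <- config$child_mix[sv$child] * c_visits
  qty <- round(c(m_qty, c_qty))
  qty <- qty[qty > 0]
  drug_items <- tibble::tibble(
    service = names(qty),
    quantity = unname(qty),
    unit_price = unname(prices[names(qty)]) * jitter_ln(length(qty), cv)
  )

  # ledger totals sized so the costing pipeline recovers the targets in
  # expectation: annual component cost = target * visits / weight, with
  # the realized weight visits_mch / visits_total so that the noiseless
  # pipeline recovers the targets exactly despite visit rounding
  tuc <- config$target_unit_costs
  scale_up <- visits_total
  personnel <- tuc[["personnel"]] * scale_up * jitter_ln(1, cv)
  overhead <- tuc[["overhead"]] * scale_up * jitter_ln(1, cv)
  cap_annual <- tuc[["capital"]] * scale_up * jitter_ln(1, cv)
  shares <- c(building = 0.5, transport = 0.2,
              medical_equipment = 0.2, other = 0.1)
  lives <- pp$useful_life_defaults[names(shares)]
  r <- pp$discount_rate
  ann_factor <- if (r == 0) 1 / lives else r / (1 - (1 + r)^(-lives))
  capital_items <- tibble::tibble(
    category = names(shares),
    replacement_cost = unname(cap_annual * shares / ann_factor),
    useful_life = unname(lives),
    acquisition_year = 2010
  )

  facility_ledger(
    facility_id = sprintf("fac%03d", id),
    capital_items = capital_items,
    personnel_annual = personnel,
    overhead_annual = overhead,
    drug_line_items = drug_items,
    visits_total = visits_total,
    visits_mch = visits_mch,
    maternal_service_mix = config$maternal_mix,
    child_service_mix = config$child_mix
  )
}

#' Generate synthetic facility cost ledgers
#'
#' Deterministic for a fixed config and seed. With `noise_cv = 0` the
#' costing pipeline recovers `target_unit_costs` exactly; with noise the
#' recovery error shrinks as facilities are pooled.
#'
#' @param config A [synthetic_config()].
#' @return A list of [facility_ledger()] objects.
#' @examples
#' ledgers <- generate_facility_ledgers(synthetic_config(seed = 7,
#'                                                       n_facilities = 5))
#' cost_state(ledgers, n_standard_facilities = 255)
#' @export
generate_facility_ledgers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    lapply(seq_len(config$n_facilities),
           function(i) generate_one_ledger(config, i))
  })
}

#' Generate a full synthetic input bundle for a study-like state
#'
#' Presets (visit volumes, utilization weight, per-visit component cost
#' targets, calibrated service mixes, facility count) come from the
#' built-in reference values for the named state, so the end-to-end
#' pipeline on the bundle reproduces that state's published drug-only
#' package unit costs up to the configured noise.
#'
#' @param state_like One of `"Imo"`, `"Kaduna"`, `"Niger"`.
#' @param seed Integer RNG seed.
#' @param n_facilities Facilities to simulate (default 50).
#' @param noise_cv Noise level (default 0.1).
#' @param dir Optional directory: when given, the profile, price list
#'   and per-facility ledgers are also written as delimited files.
#' @return A list with `profile` (one-row state profile), `config`,
#'   `ledgers`, `price_list`, `maternal_mix`, `child_mix`.
#' @export
generate_state_bundle <- function(state_like = c("Imo", "Kaduna", "Niger"),
                                  seed = 1, n_facilities = 50,
                                  noise_cv = 0.1, dir = NULL) {
  state_like <- match.arg(state_like)
  fx <- reference_fixtures()
  prof <- fx$state_profiles[fx$state_profiles$state == state_like, ]
  cu <- fx$component_unit_costs
  cu <- cu[cu$state == state_like, ]
  ut <- fx$utilization[fx$utilization$state == state_like, ]
  mixes <- state_service_mixes(state_like)
  config <- synthetic_config(
    seed = seed, n_facilities = n_facilities, mch_weight = prof$mch_weight,
    maternal_visit_mean = ut$maternal_visits,
    child_visit_mean = ut$child_visits,
    target_unit_costs = c(capital = cu$capital, personnel = cu$personnel,
                          overhead = cu$overhead),
    noise_cv = noise_cv, price_list = fx$price_list[c("service", "naira_cost")],
    maternal_mix = mixes$maternal, child_mix = mixes$child
  )
  ledgers <- generate_facility_ledgers(config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(prof, file.path(dir, "state_profile.csv"))
    readr::write_csv(config$price_list, file.path(dir, "price_list.csv"))
    for (lg in ledgers) {
      write_facility_ledger(lg, file.path(dir, lg$facility_id))
    }
  }
  list(profile = prof, config = config, ledgers = ledgers,
       price_list = config$price_list,
       maternal_mix = mixes$maternal, child_mix = mixes$child)
}

#' Estimate prices, mixes and unit costs back from ledgers
#'
#' The reverse of the generator: pools the facility registers and
#' re-estimates the drug price list (spend over quantity per service),
#' the service utilization mixes (quantity shares, with pregnancies
#' proxied by delivery counts), and the per-visit component unit costs
#' (via [cost_state()]). Feeding the estimates into
#' [maternal_package_cost()] / [child_package_cost()] closes the loop
#' from raw registers to package unit costs.
#'
#' @param ledgers A list of [facility_ledger()] objects.
#' @param n_standard_facilities Standard PHC facilities for state
#'   scale-up.
#' @param params A [costing_params()] object.
#' @return A list with `price_list` (tibble), `maternal_mix`,
#'   `child_mix`, `state_costs` (from [cost_state()]), and the derived
#'   `maternal_package`, `child_package` drugs-only unit costs.
#' @export
estimate_from_ledgers <- function(ledgers, n_standard_facilities,
                                  params = costing_params()) {
  drugs <- purrr::map_dfr(ledgers, function(lg) lg$drug_line_items)
  pooled <- dplyr::summarise(
    dplyr::group_by(drugs, .data$service),
    spend = sum(.data$quantity * .data$unit_price),
    quantity = sum(.data$quantity),
    .groups = "drop"
  )
  pooled$price <- pooled$spend / pooled$quantity
  sv <- package_services()
  price_list <- tibble::tibble(service = pooled$service,
                               naira_cost = pooled$price)
  qty <- stats::setNames(pooled$quantity, pooled$service)
  pregnancies <- qty[["normal_delivery"]]
  opt <- intersect(sv$maternal_optional, names(qty))
  maternal_mix <- stats::setNames(qty[opt] / pregnancies, opt)
  ch <- intersect(sv$child, names(qty))
  child_mix <- stats::setNames(qty[ch] / sum(qty[ch]), ch)
  state_costs <- cost_state(ledgers, n_standard_facilities, params)
  list(
    price_list = price_list,
    maternal_mix = maternal_mix,
    child_mix = child_mix,
    state_costs = state_costs,
    maternal_package = maternal_package_cost(price_list, maternal_mix, params),
    child_package = child_package_cost(price_list,
                                       child_mix / sum(child_mix), params)
  )
}
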