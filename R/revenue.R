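#' One state's share of a BHCPF component
#'
#' `crf_one_percent * fraction / n_sharing_units`, unrounded; round
#' half-up only at display.
#'
#' @param alloc A [fund_allocation()] object.
#' @param fraction BHCPF fraction in \[0, 1\] (e.g. 0.50 for the NHIS
#'   component).
#' @return Naira, unrounded. Vectorized over `fraction`.
#' @examples
#' round_half_up(state_share(fund_allocation(), 0.50)) # 521,013,514
#' @export
state_share <- function(alloc, fraction) {
  stopifnot(inherits(alloc, "fund_allocation"))
  check_proportion(fraction, "fraction")
  alloc$crf_one_percent * fraction / alloc$n_sharing_units
}

#' Add counterpart funding to a revenue base
#'
#' Counterpart funding from states and LGAs is modelled as a matching
#' rate on the (unrounded) BHCPF revenue base: `base * (1 + rate)`.
#'
#' @param base Naira revenue base, unrounded.
#' @param rate Counterpart rate, nonnegative (0.25 in the published
#'   scenarios).
#' @return Naira, unrounded.
#' @export
apply_counterpart <- function(base, rate) {
  check_number(base, "base")
  check_number(rate, "rate", min = 0)
  base * (1 + rate)
}

#' Scenario presets
#'
#' The published scenario grid: letters a-f give the revenue recipe
#' (BHCPF fraction 0.50 / 0.70 / 0.95, without or with 25% counterpart
#' funding) and the leading digit the cost-component set — scenario 1
#' covers drugs and consumables only, scenario 2 adds overheads,
#' scenario 3 all components plus the state/LGA budget and IGR revenue
#' sources.
#'
#' @param ids Optional character vector of scenario ids (e.g. `"1a"`)
#'   to subset; unknown ids raise a configuration error.
#' @return A tibble with columns `scenario_id`, `bhcpf_fraction`,
#'   `counterpart_rate`, `include_state_budget`, `include_lga_budget`,
#'   `include_igr`, `component_set`.
#' @examples
#' scenario_presets(c("1a", "1f"))
#' @export
scenario_presets <- function(ids = NULL) {
  letters6 <- letters[1:6]
  recipe <- tibble::tibble(
    letter = letters6,
    bhcpf_fraction = c(0.50, 0.70, 0.95, 0.50, 0.70, 0.95),
    counterpart_rate = c(0, 0, 0, 0.25, 0.25, 0.25)
  )
  grid <- tidyr::crossing(
    tibble::tibble(family = 1:3,
                   component_set = c("drugs_only", "drugs_overheads",
                                     "all_components"),
                   include_extra = c(FALSE, FALSE, TRUE)),
    recipe
  )
  out <- dplyr::transmute(
    grid,
    scenario_id = paste0(.data$family, .data$letter),
    bhcpf_fraction = .data$bhcpf_fraction,
    counterpart_rate = .data$counterpart_rate,
    include_state_budget = .data$include_extra,
    include_lga_budget = .data$include_extra,
    include_igr = .data$include_extra,
    component_set = .data$component_set
  )
  out <- dplyr::arrange(out, .data$scenario_id)
  if (!is.null(ids)) {
    unknown <- setdiff(ids, out$scenario_id)
    if (length(unknown)) {
      abort_config(paste0("Unknown scenario id(s): ",
                          paste(unknown, collapse = ", ")))
    }
    out <- out[match(ids, out$scenario_id), ]
  }
  out
}

#' Available revenue under a scenario
#'
#' The state's BHCPF share at the scenario's fraction, grossed up by the
#' counterpart rate, plus whichever optional state-level revenue
#' components the scenario includes.
#'
#' @param spec A one-row data frame as returned by [scenario_presets()]
#'   (or a named list with the same fields).
#' @param alloc A [fund_allocation()] object.
#' @param state_inputs Optional named list/one-row data frame with
#'   `state_phc_budget`, `lga_phc_budget_scaled`, `igr_scaled`
#'   (Naira/yr); zeros when omitted.
#' @param counterpart_base How counterpart funding is computed:
#'   `"scenario_share"` (default, rate times the scenario's BHCPF
#'   revenue, the convention of the published scenario tables) or
#'   `"nphcda_component"` (rate times the NPHCDA 45% share, the
#'   convention stated in the published methods text).
#' @return Naira, unrounded; round half-up at display.
#' @examples
#' s <- scenario_presets("1d")
#' round_half_up(scenario_revenue(s, fund_allocation())) # 651,266,892
#' @export
scenario_revenue <- function(spec, alloc = fund_allocation(),
                             state_inputs = NULL,
                             counterpart_base = c("scenario_share",
                                                  "nphcda_component")) {
  counterpart_base <- match.arg(counterpart_base)
  spec <- as.list(spec)
  need <- c("bhcpf_fraction", "counterpart_rate", "include_state_budget",
            "include_lga_budget", "include_igr")
  if (!all(need %in% names(spec))) {
    abort_config(paste("Scenario spec must provide:",
                       paste(need, collapse = ", ")))
  }
  base <- state_share(alloc, spec$bhcpf_fraction)
  rev <- if (counterpart_base == "scenario_share") {
    apply_counterpart(base, spec$counterpart_rate)
  } else {
    base + spec$counterpart_rate * state_share(alloc, alloc$nphcda_fraction)
  }
  si <- as.list(state_inputs %||% list())
  get0n <- function(nm) {
    v <- si[[nm]] %||% 0
    check_number(v, nm, min = 0)
    v
  }
  if (isTRUE(spec$include_state_budget)) rev <- rev + get0n("state_phc_budget")
  if (isTRUE(spec$include_lga_budget)) rev <- rev + get0n("lga_phc_budget_scaled")
  if (isTRUE(spec$include_igr)) rev <- rev + get0n("igr_scaled")
  rev
}
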