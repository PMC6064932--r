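#' Project a population forward by geometric growth
#'
#' Annual compounding at a single state-level growth rate:
#' `census_population * (1 + growth_rate/100)^n_years`. The unrounded
#' value is returned; round only for display.
#'
#' @param census_population Base-year population (persons), positive.
#' @param growth_rate Growth rate in percent per annum, nonnegative.
#' @param n_years Number of years to project, nonnegative.
#' @return Projected population (persons, unrounded). Vectorized.
#' @examples
#' project_population(1000, 3, 1) # 1030
#' @export
project_population <- function(census_population, growth_rate, n_years) {
  check_number(census_population, "census_population")
  check_number(growth_rate, "growth_rate", min = 0)
  check_number(n_years, "n_years")
  if (any(census_population <= 0)) {
    rlang::abort("`census_population` must be positive.",
                 class = "mchfundr_invalid_input")
  }
  if (any(n_years < 0)) {
    rlang::abort("`n_years` must be nonnegative.",
                 class = "mchfundr_invalid_input")
  }
  census_population * (1 + growth_rate / 100)^n_years
}

#' Derive target beneficiary counts from a projected population
#'
#' Applies the pregnant and under-five fractions to the unrounded
#' projected population, rounds each count half-up independently, and
#' reports the combined MCH target as the sum of the rounded parts.
#'
#' @param population Projected population (persons), positive. Vectorized.
#' @param params A [demography_params()] object.
#' @return A tibble with columns `pregnant_women`, `under_five`,
#'   `all_mch` (integer-valued persons).
#' @examples
#' derive_targets(5224573.76)
#' @export
derive_targets <- function(population, params = demography_params()) {
  stopifnot(inherits(params, "demography_params"))
  check_number(population, "population")
  if (any(population <= 0)) {
    rlang::abort("`population` must be positive.",
                 class = "mchfundr_invalid_input")
  }
  pw <- round_half_up(params$pregnant_fraction * population)
  u5 <- round_half_up(params$under5_fraction * population)
  tibble::tibble(pregnant_women = pw, under_five = u5, all_mch = pw + u5)
}

#' Scale target counts to the vulnerable (below-poverty-line) subset
#'
#' @param targets A tibble as returned by [derive_targets()] (columns
#'   `pregnant_women`, `under_five`, `all_mch`).
#' @param fraction Proportion of beneficiaries below the poverty line,
#'   in \[0, 1\] (default 0.63).
#' @return A tibble of the same shape with each count scaled and rounded
#'   half-up.
#' @examples
#' vulnerable_subset(tibble::tibble(pregnant_women = 398837,
#'                                  under_five = 1595347,
#'                                  all_mch = 1994184))
#' @export
vulnerable_subset <- function(targets, fraction = 0.63) {
  check_proportion(fraction, "fraction")
  need <- c("pregnant_women", "under_five", "all_mch")
  if (!all(need %in% names(targets))) {
    abort_config("`targets` must have columns pregnant_women, under_five, all_mch.")
  }
  dplyr::mutate(tibble::as_tibble(targets),
                dplyr::across(dplyr::all_of(need),
                              ~ round_half_up(.x * fraction)))
}

#' Project populations and derive targets for a table of states
#'
#' Data-frame-first wrapper composing [project_population()] and
#' [derive_targets()] over one row per state.
#'
#' @param states A data frame with columns `state`, `census_population`,
#'   `growth_rate` (percent/yr), e.g. from [read_state_profiles()] or
#'   [study_state_profiles()].
#' @param params A [demography_params()] object.
#' @return The input tibble with added columns `projected_population`
#'   (unrounded), `pregnant_women`, `under_five`, `all_mch`,
#'   `all_mch_vulnerable`.
#' @examples
#' project_targets(study_state_profiles())
#' @export
project_targets <- function(states, params = demography_params()) {
  stopifnot(inherits(params, "demography_params"))
  need <- c("state", "census_population", "growth_rate")
  if (!all(need %in% names(states))) {
    abort_config(paste("`states` must have columns:",
                       paste(need, collapse = ", ")))
  }
  n_years <- params$target_year - params$base_year
  states <- tibble::as_tibble(states)
  states$projected_population <-
    project_population(states$census_population, states$growth_rate, n_years)
  tg <- derive_targets(states$projected_population, params)
  vg <- vulnerable_subset(tg, params$vulnerable_fraction)
  dplyr::bind_cols(states, tg,
                   tibble::tibble(all_mch_vulnerable = vg$all_mch))
}

#' Read state demographic and infrastructure profiles
#'
#' Expects a delimited file with one row per state and columns
#' `state`, `census_population`, `growth_rate`, `n_standard_facilities`,
#' `n_lgas`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_state_profiles <- function(path) {
  prof <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("state", "census_population", "growth_rate",
            "n_standard_facilities", "n_lgas")
  missing <- setdiff(need, names(prof))
  if (length(missing)) {
    abort_config(paste0("State profile file is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(prof$census_population <= 0) || any(prof$growth_rate < 0) ||
      any(prof$n_standard_facilities <= 0)) {
    rlang::abort("Invalid state profile: populations and facility counts must be positive, growth rates nonnegative.",
                 class = "mchfundr_invalid_input")
  }
  tibble::as_tibble(prof[need])
}
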