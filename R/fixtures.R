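# Built-in reference values for the three study states (Imo, Kaduna,
# Niger), 2015 levels, transcribed verbatim from the published
# three-state BHCPF feasibility assessment these methods reproduce.
# Census base populations are back-derived from the printed beneficiary
# targets (see the methods vignette); everything else is as printed.

#' Built-in state profiles for the three study states
#'
#' Census base populations (2006) are back-derived so that projection to
#' 2015 reproduces the published target-beneficiary counts; growth
#' rates, standard-facility counts and MCH utilization weights are the
#' published values.
#'
#' @return A tibble with columns `state`, `census_population`,
#'   `growth_rate`, `n_standard_facilities`, `n_lgas`, `mch_weight`.
#' @examples
#' study_state_profiles()
#' @export
study_state_profiles <- function() {
  tibble::tibble(
    state = c("Imo", "Kaduna", "Niger"),
    census_population = c(3934899, 6113505, 3950248),
    growth_rate = c(3.2, 3.0, 3.4),
    n_standard_facilities = c(418, 255, 274),
    n_lgas = c(27, 23, 25),
    mch_weight = c(0.83, 0.85, 0.90)
  )
}

#' Drug-and-consumable price list for the benefit package
#'
#' Uniform 2015 prices per service episode in Naira, sourced from a
#' state drug-revolving-fund price list. Neonatal jaundice carries no
#' published price and is excluded from the package.
#'
#' @return A tibble with columns `service`, `group`, `naira_cost`.
#' @examples
#' study_price_list()
#' @export
study_price_list <- function() {
  tibble::tibble(
    service = c("antenatal_care", "normal_delivery", "postnatal_care",
                "malaria_in_pregnancy", "hypertension_in_pregnancy",
                "postpartum_hemorrhage", "family_planning",
                "child_malaria", "pneumonia", "diarrhea",
                "routine_immunization", "measles"),
    group = rep(c("maternal", "child"), c(7, 5)),
    naira_cost = c(2837.6, 1503.2, 339.8, 423.5, 1620.8, 507.8, 365.7,
                   472.4, 875.5, 443.1, 71.2, 100.0)
  )
}

scenario1_table <- function(scenario_id, available, rows) {
  out <- tibble::as_tibble(rows)
  out$scenario_id <- scenario_id
  out$available <- available
  out[c("scenario_id", "state", "group", "unit_cost_display", "unit_cost_usd",
        "targets", "required", "available", "lives_covered", "gap",
        "additional_pct")]
}

s1_rows <- function(m) {
  tibble::tibble(
    group = rep(c("maternal", "child", "all_mch", "all_mch_vulnerable"),
                each = 3),
    state = rep(c("Imo", "Kaduna", "Niger"), 4),
    unit_cost_display = m[, 1], unit_cost_usd = m[, 2], targets = m[, 3],
    required = m[, 4], lives_covered = m[, 5], gap = m[, 6],
    additional_pct = m[, 7]
  )
}

#' Reference fixtures: published tables and scalars
#'
#' Immutable copies of the published inputs and Scenario-1 results for
#' the three study states: the service price list, state profiles,
#' per-visit component unit costs, package costs, the four Scenario-1
#' feasibility tables (scenarios 1a, 1c, 1d, 1f) and the revenue
#' scalars. Used by the test suite to check that the pipeline
#' regenerates the published results.
#'
#' Known quirks carried verbatim: the Imo ALL-MCH target (1,306,143)
#' differs by 1 from the sum of its printed parts; the scenario-1d
#' table's child rows print the combined (ALL-MCH) unit costs in the
#' unit-cost column; Imo's personnel and overhead totals print the same
#' number.
#'
#' @return A named list of tibbles and scalars; see Details.
#' @examples
#' fx <- reference_fixtures()
#' names(fx)
#' @export
reference_fixtures <- function() {
  t1a <- s1_rows(matrix(c(
    4827, 15.8, 261229, 1260836278, 107937, -739822765, 142,
    4774, 15.7, 398837, 1903905766, 109144, -1382892252, 265,
    4759, 15.6, 266857, 1269963038, 109481, -748949524, 144,
    385, 1.3, 1044915, 402574841, 1352332, 118438672, -23,
    344, 1.1, 1595347, 548852075, 1514429, -27838562, 5,
    843, 2.8, 1067430, 900339922, 617706, -379326408, 73,
    1274, 4.2, 1306143, 1663411119, 409110, -1142397606, 219,
    1230, 4.0, 1994184, 2452757841, 423603, -1931744328, 371,
    1627, 5.3, 1334287, 2170302960, 320315, -1649289446, 317,
    1274, 4.2, 822870, 1048336495, 408959, -527322981, 101,
    1230, 4.0, 1256336, 1545293182, 423588, -1024279668, 197,
    1627, 5.3, 840601, 1367657518, 320230, -846644044, 162
  ), ncol = 7, byrow = TRUE))
  t1c <- s1_rows(matrix(c(
    4827, 15.8, 261229, 1260836278, 205100, -270910603, 27,
    4774, 15.7, 398837, 1903905766, 207373, -913980090, 92,
    4759, 15.6, 266857, 1269963038, 208013, -280037362, 28,
    385, 1.3, 1044915, 402574841, 2569430, 587350835, -59,
    344, 1.1, 1595347, 548852075, 2877414, 441073601, -45,
    843, 2.8, 1067430, 900339922, 1173641, 89585754, -9,
    1274, 4.2, 1306143, 1663411119, 777309, -673485444, 68,
    1230, 4.0, 1994184, 2452757841, 804847, -1462832165, 148,
    1627, 5.3, 1334287, 2170302960, 608599, -1180377284, 119,
    1274, 4.2, 822870, 1048336495, 777022, -58410819, 6,
    1230, 4.0, 1256336, 1545293182, 804818, -555367506, 56,
    1627, 5.3, 840601, 1367657518, 608436, -377731842, 38
  ), ncol = 7, byrow = TRUE))
  t1d <- s1_rows(matrix(c(
    4827, 15.8, 261229, 1260836278, 134934, -609569386, 94,
    4774, 15.7, 398837, 1903905766, 136430, -1252638874, 192,
    4759, 15.6, 266857, 1269963038, 136851, -618696146, 95,
    1274, 4.2, 1044915, 402574841, 1690415, 248692051, -38,
    1230, 4.0, 1595347, 548852075, 1893036, 102414817, -16,
    1627, 5.3, 1067430, 900339922, 772132, -249073030, 38,
    1274, 4.2, 1306143, 1663411119, 511388, -1012144227, 155,
    1230, 4.0, 1994184, 2452757841, 529504, -1801490949, 277,
    1627, 5.3, 1334287, 2170302960, 400394, -1519036068, 233,
    1274, 4.2, 822870, 1048336495, 511198, -397069603, 61,
    1230, 4.0, 1256336, 1545293182, 529485, -894026290, 137,
    1627, 5.3, 840601, 1367657518, 400287, -716390626, 110
  ), ncol = 7, byrow = TRUE))
  t1f <- s1_rows(matrix(c(
    4827, 15.8, 261229, 1260836278, 256374, -23429184, 2,
    4774, 15.7, 398837, 1903905766, 259216, -666498671, 54,
    4759, 15.6, 266857, 1269963038, 260016, -32555943, 3,
    385, 1.3, 1044915, 402574841, 3211788, 834832254, -67,
    344, 1.1, 1595347, 548852075, 3596768, 688555020, -56,
    843, 2.8, 1067430, 900339922, 1467052, 337067173, -27,
    1274, 4.2, 1306143, 1663411119, 971637, -426004025, 34,
    1230, 4.0, 1994184, 2452757841, 1006058, -1215350746, 98,
    1627, 5.3, 1334287, 2170302960, 760749, -932895865, 75,
    1274, 4.2, 822870, 1048336495, 971277, 189070600, -15,
    1230, 4.0, 1256336, 1545293182, 1006022, -307886087, 25,
    1627, 5.3, 840601, 1367657518, 760545, -130250423, 11
  ), ncol = 7, byrow = TRUE))

  scenario1 <- dplyr::bind_rows(
    scenario1_table("1a", 521013514, t1a),
    scenario1_table("1c", 989925676, t1c),
    scenario1_table("1d", 651266892, t1d),
    scenario1_table("1f", 1237407095, t1f)
  )

  states <- c("Imo", "Kaduna", "Niger")
  list(
    price_list = study_price_list(),
    state_profiles = study_state_profiles(),
    targets = tibble::tibble(
      state = states,
      pregnant_women = c(261229, 398837, 266857),
      under_five = c(1044915, 1595347, 1067430),
      all_mch = c(1306143, 1994184, 1334287),
      all_mch_vulnerable = c(822870, 1256336, 840601)
    ),
    component_unit_costs = tibble::tibble(
      state = states,
      capital = c(133.1, 43.9, 81.3),
      personnel = c(2506.6, 676.5, 1748.0),
      overhead = c(80.1, 9.7, 19.9)
    ),
    component_state_totals = tibble::tibble(
      state = states,
      capital = c(248852530, 149420695, 182132833),
      drugs = c(454991616, 913922222, 925283827),
      personnel = c(149889054, 2304646474, 3916955570),
      overhead = c(149889054, 32910644, 44514106)
    ),
    package_costs = tibble::tibble(
      state = states,
      maternal_drugs_display = c(4827, 4774, 4759),
      child_drugs_display = c(385, 344, 843),
      # unrounded drug-only unit costs, recovered as required / targets
      maternal_drugs = c(1260836278 / 261229, 1903905766 / 398837,
                         1269963038 / 266857),
      child_drugs = c(402574841 / 1044915, 548852075 / 1595347,
                      900339922 / 1067430),
      maternal_all_components = c(21145.5, 9153.6, 8729.6),
      child_all_components = c(8544.8, 2534.0, 4709.0)
    ),
    utilization = tibble::tibble(
      state = states,
      maternal_visits = c(817, 4690, 2623),
      child_visits = c(3658, 8671, 5555)
    ),
    revenue = list(
      crf_one_percent = 38555e6,
      nhis_state_share = 521013514,
      nphcda_state_share = 468912162,
      counterpart_printed = 24481419,  # matches neither convention; unused
      total_state_revenue = stats::setNames(
        c(7013884907, 9968254995, 5202936421), states)
    ),
    scenario1_tables = scenario1
  )
}

#' Stable checksum over the reference fixtures
#'
#' A 31-bit polynomial hash over every number in [reference_fixtures()],
#' asserted in the test suite to guard against accidental edits to the
#' transcribed tables.
#'
#' @return A single integer-valued double.
#' @export
fixture_checksum <- function() {
  fx <- reference_fixtures()
  nums <- unlist(lapply(fx, function(el) {
    if (is.data.frame(el)) unlist(el[vapply(el, is.numeric, TRUE)])
    else unlist(el[vapply(el, is.numeric, TRUE)])
  }), use.names = FALSE)
  txt <- paste(formatC(nums, format = "fg", digits = 15), collapse = "|")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 31 + k) %% 2147483647
  h
}
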