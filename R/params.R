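#' Demographic parameters for target-beneficiary derivation
#'
#' Fractions of a projected state population that make up the target
#' groups of the benefit package, and the projection window. Defaults are
#' the planning conventions used for the three study states: pregnant
#' women are 5% of the population, under-five children 20%, and 63% of
#' beneficiaries fall below the poverty line (the "vulnerable" subset).
#'
#' @param pregnant_fraction Proportion of the population who are pregnant
#'   women in the target year (default 0.05).
#' @param under5_fraction Proportion who are under-five children
#'   (default 0.20).
#' @param vulnerable_fraction Proportion of beneficiaries below the
#'   poverty line (default 0.63).
#' @param base_year Census base year (default 2006).
#' @param target_year Year populations are projected to (default 2015).
#' @return A list of class `demography_params`.
#' @examples
#' demography_params()
#' @export
demography_params <- function(pregnant_fraction = 0.05,
                              under5_fraction = 0.20,
                              vulnerable_fraction = 0.63,
                              base_year = 2006,
                              target_year = 2015) {
  check_proportion(pregnant_fraction, "pregnant_fraction")
  check_proportion(under5_fraction, "under5_fraction")
  check_proportion(vulnerable_fraction, "vulnerable_fraction")
  if (pregnant_fraction + under5_fraction > 1) {
    rlang::abort("`pregnant_fraction` + `under5_fraction` must not exceed 1.",
                 class = "mchfundr_invalid_input")
  }
  if (target_year < base_year) {
    rlang::abort("`target_year` must not precede `base_year`.",
                 class = "mchfundr_invalid_input")
  }
  structure(
    list(pregnant_fraction = pregnant_fraction,
         under5_fraction = under5_fraction,
         vulnerable_fraction = vulnerable_fraction,
         base_year = base_year,
         target_year = target_year),
    class = "demography_params"
  )
}

#' Costing parameters for the benefit package
#'
#' Tunables of the bottom-up costing model: the discount rate and default
#' useful lives used to annualize capital stock, the Naira/US$ exchange
#' rate used at display, the visit schedule of the package (four
#' antenatal visits plus delivery and one postnatal visit for a
#' pregnancy; three facility visits per child-year), and the
#' mother/child mixing probabilities used for the combined unit cost.
#'
#' @param discount_rate Annual discount rate for capital annualization
#'   (default 0.03).
#' @param useful_life_defaults Named numeric vector of useful lives in
#'   years per capital category (`building`, `transport`,
#'   `medical_equipment`, `other`).
#' @param exchange_rate Naira per US$ used for display (default 305.5).
#' @param anc_visits Antenatal visits per pregnancy (default 4).
#' @param child_visits_per_year Facility visits per child-year (default 3).
#' @param p_mother Probability a beneficiary is a mother (default 0.2).
#' @param p_child Probability a beneficiary is a child (default 0.8);
#'   must sum to 1 with `p_mother`.
#' @param anc_drug_pricing Whether the antenatal drug price covers the
#'   full course per pregnancy (`"course"`, default) or is charged at
#'   each antenatal visit (`"per_visit"`). Non-drug components always
#'   accrue per visit.
#' @return A list of class `costing_params`.
#' @examples
#' costing_params(discount_rate = 0.05)
#' @export
costing_params <- function(discount_rate = 0.03,
                           useful_life_defaults = c(building = 30,
                                                    transport = 10,
                                                    medical_equipment = 5,
                                                    other = 5),
                           exchange_rate = 305.5,
                           anc_visits = 4,
                           child_visits_per_year = 3,
                           p_mother = 0.2,
                           p_child = 0.8,
                           anc_drug_pricing = c("course", "per_visit")) {
  check_number(discount_rate, "discount_rate", min = 0)
  check_number(exchange_rate, "exchange_rate")
  if (exchange_rate <= 0) {
    rlang::abort("`exchange_rate` must be positive.",
                 class = "mchfundr_invalid_input")
  }
  check_number(anc_visits, "anc_visits", min = 1)
  check_number(child_visits_per_year, "child_visits_per_year", min = 0)
  check_proportion(p_mother, "p_mother")
  check_proportion(p_child, "p_child")
  if (abs(p_mother + p_child - 1) > 1e-12) {
    rlang::abort("`p_mother` + `p_child` must equal 1.",
                 class = "mchfundr_invalid_input")
  }
  stopifnot(all(c("building", "transport", "medical_equipment", "other") %in%
                  names(useful_life_defaults)))
  check_number(useful_life_defaults, "useful_life_defaults", min = 1)
  structure(
    list(discount_rate = discount_rate,
         useful_life_defaults = useful_life_defaults,
         exchange_rate = exchange_rate,
         anc_visits = anc_visits,
         child_visits_per_year = child_visits_per_year,
         p_mother = p_mother,
         p_child = p_child,
         anc_drug_pricing = match.arg(anc_drug_pricing)),
    class = "costing_params"
  )
}

#' BHCPF allocation rule
#'
#' The statutory split of the Basic Health Care Provision Fund (1% of the
#' Consolidated Revenue Fund) between its three recipients — NHIS 50%,
#' NPHCDA 45%, FMOH 5% — shared equally across the 36 states and the
#' Federal Capital Territory.
#'
#' @param crf_one_percent 1% of the Consolidated Revenue Fund, in Naira
#'   (default 38,555,000,000, the 2015 level).
#' @param nhis_fraction,nphcda_fraction,fmoh_fraction Recipient fractions;
#'   must sum to 1.
#' @param n_sharing_units Number of equal sharing units (default 37).
#' @return A list of class `fund_allocation`.
#' @examples
#' fund_allocation()
#' @export
fund_allocation <- function(crf_one_percent = 38555e6,
                            nhis_fraction = 0.50,
                            nphcda_fraction = 0.45,
                            fmoh_fraction = 0.05,
                            n_sharing_units = 37) {
  check_number(crf_one_percent, "crf_one_percent", min = 0)
  check_proportion(nhis_fraction, "nhis_fraction")
  check_proportion(nphcda_fraction, "nphcda_fraction")
  check_proportion(fmoh_fraction, "fmoh_fraction")
  if (abs(nhis_fraction + nphcda_fraction + fmoh_fraction - 1) > 1e-12) {
    rlang::abort("Recipient fractions must sum to 1.",
                 class = "mchfundr_invalid_input")
  }
  check_number(n_sharing_units, "n_sharing_units", min = 1)
  structure(
    list(crf_one_percent = crf_one_percent,
         nhis_fraction = nhis_fraction,
         nphcda_fraction = nphcda_fraction,
         fmoh_fraction = fmoh_fraction,
         n_sharing_units = n_sharing_units),
    class = "fund_allocation"
  )
}
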