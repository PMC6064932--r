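# Service-mix calibration. The published results give each state's
# package unit cost but not the underlying per-service utilization mix,
# so the mix is recovered once by constrained least squares against the
# published unit costs and shipped as preset constants
# (state_service_mixes()). The calibration functions remain exported so
# the presets can be re-derived and so users can calibrate to their own
# unit-cost targets.

#' Calibrate maternal optional-service weights to a unit-cost target
#'
#' The maternal drug cost is the fixed ANC + delivery + PNC base plus a
#' price-weighted sum of optional services (family planning and the
#' pregnancy complications). Given a target drug-only unit cost, returns
#' the minimal-norm nonnegative weight vector that reproduces it
#' exactly: `w = excess * p / sum(p^2)` over the optional-service prices
#' `p`, the least-squares solution of the underdetermined system.
#'
#' @param target_unit_cost Target maternal drugs-only cost per pregnancy
#'   (Naira), at least the core-service base.
#' @param prices Price list (see [maternal_package_cost()]).
#' @param params A [costing_params()] object.
#' @return Named numeric vector of weights over the optional maternal
#'   services, each in \[0, 1\].
#' @export
calibrate_maternal_mix <- function(target_unit_cost,
                                   prices = study_price_list(),
                                   params = costing_params()) {
  sv <- package_services()
  core <- price_lookup(prices, sv$maternal_core)
  opt <- price_lookup(prices, sv$maternal_optional)
  base <- if (params$anc_drug_pricing == "per_visit") {
    core[["antenatal_care"]] * params$anc_visits
  } else {
    core[["antenatal_care"]]
  }
  base <- base + core[["normal_delivery"]] + core[["postnatal_care"]]
  excess <- target_unit_cost - base
  if (excess < 0) {
    abort_config("`target_unit_cost` is below the core-service base; no nonnegative mix exists.")
  }
  w <- excess * opt / sum(opt^2)
  if (any(w > 1)) {
    abort_config("`target_unit_cost` too large: calibrated weights exceed 1.")
  }
  w
}

# min ||w - uniform||^2 s.t. sum(w) = 1, p.w = t, w >= 0 — closed form on
# the active support, dropping the most negative coordinate until all
# weights are nonnegative (exact for this problem size).
simplex_mix <- function(p, t) {
  if (t < min(p) || t > max(p)) {
    abort_config("Target per-visit price lies outside the price range; no convex mix exists.")
  }
  keep <- seq_along(p)
  repeat {
    ps <- p[keep]
    cc <- ps - mean(ps)
    b <- if (sum(cc^2) > 0) (t - mean(ps)) / sum(cc^2) else 0
    w <- 1 / length(ps) + b * cc
    if (all(w >= -1e-12)) {
      out <- stats::setNames(numeric(length(p)), names(p))
      out[keep] <- pmax(w, 0)
      return(out)
    }
    keep <- keep[-which.min(w)]
  }
}

#' Calibrate the child service mix to a unit-cost target
#'
#' Finds the per-visit utilization mix over the child services (a point
#' on the probability simplex) whose expected drug price reproduces a
#' target child package cost, choosing the mix closest to uniform in
#' least squares.
#'
#' @param target_unit_cost Target child drugs-only cost per child-year
#'   (Naira).
#' @param prices Price list.
#' @param params A [costing_params()] object (supplies
#'   `child_visits_per_year`).
#' @return Named numeric vector over the child services, summing to 1.
#' @export
calibrate_child_mix <- function(target_unit_cost,
                                prices = study_price_list(),
                                params = costing_params()) {
  sv <- package_services()
  p <- price_lookup(prices, sv$child)
  simplex_mix(p, target_unit_cost / params$child_visits_per_year)
}

#' Preset service mixes for the three study states
#'
#' Calibrated once against the published drug-only package unit costs
#' (see [calibrate_maternal_mix()] and [calibrate_child_mix()]) and
#' frozen; a unit test asserts the calibration reproduces these
#' constants.
#'
#' @param state One of `"Imo"`, `"Kaduna"`, `"Niger"`.
#' @return A list with named numeric vectors `maternal` (optional-service
#'   weights) and `child` (per-visit mix summing to 1).
#' @examples
#' state_service_mixes("Kaduna")
#' @export
state_service_mixes <- function(state = c("Imo", "Kaduna", "Niger")) {
  state <- match.arg(state)
  maternal <- list(
    Imo = c(family_planning = 0.0166907149922833,
            malaria_in_pregnancy = 0.0193287333859228,
            hypertension_in_pregnancy = 0.0739740521178362,
            postpartum_hemorrhage = 0.0231762238804524),
    Kaduna = c(family_planning = 0.0106400020947083,
               malaria_in_pregnancy = 0.0123216868665818,
               hypertension_in_pregnancy = 0.0471570013538506,
               postpartum_hemorrhage = 0.0147743862829993),
    Niger = c(family_planning = 0.00896137642205837,
              malaria_in_pregnancy = 0.0103777492883285,
              hypertension_in_pregnancy = 0.0397172515856500,
              postpartum_hemorrhage = 0.0124434972576463)
  )
  child <- list(
    Imo = c(child_malaria = 0.0436396741186054,
            pneumonia = 0,
            diarrhea = 0.0737622674593694,
            routine_immunization = 0.4561033071668830,
            measles = 0.4264947512551420),
    Kaduna = c(child_malaria = 0.0238382339195026,
               pneumonia = 0,
               diarrhea = 0.0568512604291977,
               routine_immunization = 0.4758800849669340,
               measles = 0.4434304206843660),
    Niger = c(child_malaria = 0.1793552997222018,
              pneumonia = 0.0752797784368031,
              diarrhea = 0.1869202036509097,
              routine_immunization = 0.2829402640975480,
              measles = 0.2755044540925380)
  )
  list(maternal = maternal[[state]], child = child[[state]])
}
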