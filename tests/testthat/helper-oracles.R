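# Independent oracles, deliberately naive: spreadsheet-style loops and
# brute-force searches, never calling the implementation under test.

# compound a population year by year
oracle_compound <- function(pop, growth_pct, n_years) {
  for (i in seq_len(n_years)) pop <- pop * (1 + growth_pct / 100)
  pop
}

# annuity payment P with sum_{t=1..L} P/(1+r)^t = cost, by bisection
oracle_annuity_payment <- function(cost, life, rate, tol = 1e-9) {
  pv <- function(p) sum(p / (1 + rate)^seq_len(life))
  lo <- 0
  hi <- cost * (1 + rate)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pv(mid) < cost) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# enumerate and sum every revenue component of a scenario preset
oracle_scenario_revenue <- function(preset, crf, n_units, inputs = NULL) {
  parts <- crf * preset$bhcpf_fraction / n_units
  parts <- c(parts, preset$counterpart_rate * parts)
  if (isTRUE(preset$include_state_budget)) {
    parts <- c(parts, inputs$state_phc_budget)
  }
  if (isTRUE(preset$include_lga_budget)) {
    parts <- c(parts, inputs$lga_phc_budget_scaled)
  }
  if (isTRUE(preset$include_igr)) {
    parts <- c(parts, inputs$igr_scaled)
  }
  sum(parts)
}

# smallest x (percent of CRF, 0.01 grid) whose state share at the given
# allocation fraction covers the requirement
oracle_min_crf_grid <- function(max_required, crf, n_units, fraction,
                                step = 0.01, x_max = 50) {
  for (x in seq(step, x_max, by = step)) {
    if (fraction * x * crf / n_units >= max_required) return(x)
  }
  NA_real_
}

# spreadsheet-style aggregation of ledgers: raw sums only
oracle_aggregate_ledgers <- function(ledgers, discount_rate) {
  cap <- per <- ovh <- visits <- 0
  for (lg in ledgers) {
    w <- lg$visits_mch / lg$visits_total
    a <- 0
    for (i in seq_len(nrow(lg$capital_items))) {
      cost <- lg$capital_items$replacement_cost[i]
      life <- lg$capital_items$useful_life[i]
      a <- a + if (discount_rate == 0) cost / life else
        cost * discount_rate / (1 - (1 + discount_rate)^(-life))
    }
    cap <- cap + a * w
    per <- per + lg$personnel_annual * w
    ovh <- ovh + lg$overhead_annual * w
    visits <- visits + lg$visits_mch
  }
  list(unit_capital = cap / visits, unit_personnel = per / visits,
       unit_overhead = ovh / visits)
}
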