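---
title: "Costing and funding-gap methods for a basic MCH benefit package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing and funding-gap methods for a basic MCH benefit package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mchfundr)
library(dplyr)
```

## The question the package answers

Nigeria's Basic Health Care Provision Fund (BHCPF) earmarks at least 1%
of the Consolidated Revenue Fund (CRF) for primary care, split between
the NHIS (50%), the NPHCDA (45%) and the FMOH (5%) and shared equally
across the 36 states and the Federal Capital Territory. `mchfundr` asks
whether a state's share of that fund can pay for a basic maternal and
child health (MCH) benefit package — antenatal care, facility delivery,
postnatal care, family planning, and curative plus preventive care for
under-five children — for every target beneficiary in a state, and if
not, how large the funding gap is and what share of the CRF would close
it. The built-in inputs reproduce a published three-state assessment
(Imo, Kaduna and Niger, 2015 price and revenue levels); every piece of
the machinery is configurable, so the same pipeline applies to other
states, years or packages.

## The model

The analysis composes four deterministic stages.

**Demography.** A state's population is projected from its census base
by annual geometric compounding, $P_t = P_0 (1 + g/100)^t$, with a
single state growth rate $g$ and $t$ = 9 years (2006 to 2015). Target
groups are fixed fractions of the projected population: pregnant women
5%, under-five children 20%, and a below-poverty-line ("vulnerable")
subset of 63% of beneficiaries. Counts are carried unrounded and rounded
half-up only when a person count is reported; the combined MCH target is
the sum of the two rounded group counts.

**Costing.** Facility costs split into drugs and consumables (priced
per service episode from a uniform price list), and three shared
components — capital, personnel, overheads — that are allocated to MCH
by the facility's utilization weight (MCH visits over all outpatient
visits) and divided by MCH visits to give per-visit unit costs. Capital
stock is annualized with the standard annuity factor
$A = C\,r / (1 - (1+r)^{-L})$ at a 3%/yr discount rate, with default
useful lives of 30y (buildings), 10y (transport) and 5y (equipment and
other); at $r = 0$ the straight-line $C/L$ limit applies. The maternal
package cost per pregnancy is the ANC course + delivery + postnatal care
+ utilization-weighted optional services (family planning and three
pregnancy complications), plus — when the cost-component set includes
them — the per-visit components over the six visits of the pregnancy
episode (four ANC visits, delivery, one postnatal visit). The child
package cost is three annual visits at the utilization-weighted mean
service price, plus per-visit components. A combined per-beneficiary
cost mixes the two at the 0.2/0.8 mother/child probabilities.

**Revenue.** A scenario is a recipe: a BHCPF fraction (0.50, 0.70 or
0.95 of the 1%-of-CRF pool, shared 37 ways), an optional 25% counterpart
rate from states and LGAs, and optional state budget, LGA budget and
facility IGR components. Scenario families 1/2/3 pair those recipes
with the drugs-only, drugs+overheads and all-components cost sets.
Division by 37 is the only step producing repeating decimals; all
arithmetic stays unrounded until display (IEEE doubles are exact for
the integer Naira magnitudes involved, and carry the fractional parts
to ~1e-7 Naira, far below the half-up display rounding).

**Feasibility.** For each (state, group, scenario): required = unit
cost × targets on the unrounded chain; gap = available − required
exactly; additional funds needed = −100·gap/available; lives covered =
⌊available / unit cost⌋ with the unrounded unit cost, because a
fractional person cannot be covered. The minimum-CRF solve inverts the
share formula: the smallest $x$ (in percent-of-CRF units) with
$f \cdot x \cdot \mathrm{CRF}_{1\%}/37 \ge$ the largest state
requirement is $x = 37\,R_{\max} / (f \cdot \mathrm{CRF}_{1\%})$; at
the NHIS fraction $f = 0.5$ and the largest drugs-only requirement this
gives 4.71, i.e. at least 4% of the CRF.

### Row conventions in the reference tables

Reverse-engineering the published scenario tables cell by cell fixed
three conventions that the package reproduces deliberately:

- the ALL-MCH required amount is the *sum* of the maternal and child
  required amounts (exact in all twelve state × scenario cells), so the
  row's unit cost is that sum divided by the combined target — which
  rounds to the same displayed value as the 0.2/0.8 mix;
- the vulnerable row applies the poverty fraction to the ALL-MCH row at
  its displayed whole-Naira unit cost (again exact in all cells);
- lives covered floors available over the row's unrounded unit cost.

A handful of printed cells disagree with their own row arithmetic at
the last digit: one combined target mis-sums its parts by one person,
two gap cells round an identical .49 fraction in opposite directions,
one gap cell transposes a digit relative to the only value consistent
with its printed percentage, and one lives-covered cell uses the
rounded rather than unrounded unit cost. The regeneration test
(`test-feasibility.R`) matches every cell exactly up to these
enumerated, commented exceptions; nothing is tuned to absorb them.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pregnant_fraction`, `under5_fraction` | 0.05, 0.20 | share of population | planning convention for the target groups |
| `vulnerable_fraction` | 0.63 | share of beneficiaries | poverty headcount; the published text once says 61%, but every table value uses 63% — override available |
| `discount_rate` | 0.03 | per annum | standard annuity discounting of capital |
| `useful_life_defaults` | 30/10/5/5 | years | typical economic lives by capital category |
| `exchange_rate` | 305.5 | ₦/US$ | back-derived from the published unit-cost pairs (4,827 ↔ $15.8); display only |
| `anc_visits`, `child_visits_per_year` | 4, 3 | visits | the package's visit schedule |
| `p_mother`, `p_child` | 0.2, 0.8 | probability | mother/child mix of the combined unit cost |
| `anc_drug_pricing` | `"course"` | — | the ANC price is a full course per pregnancy; `"per_visit"` charges it at each visit (the source does not disambiguate; the course reading reproduces the published unit costs) |
| `counterpart_base` | `"scenario_share"` | — | tables compute counterpart as 25% of the scenario's BHCPF revenue; the methods text says 25% of the NPHCDA component — both available, the table convention is the default because the published available amounts require it |

## Calibrated service mixes

The published results give each state's package unit cost but not the
per-service utilization mix behind it. The mix is therefore recovered
once by constrained least squares and shipped as preset constants
(`state_service_mixes()`): maternal optional-service weights are the
minimal-norm nonnegative solution of price·w = (unit cost − core base),
and the child mix is the point on the probability simplex closest to
uniform whose expected price matches the child cost per visit (closed
form with active-set clipping of negative coordinates). These presets
are *identifiable only up to the price vector* — they are one plausible
mix among many — and should be read as calibration constants, not as
observed utilization patterns. `calibrate_maternal_mix()` and
`calibrate_child_mix()` re-derive them, and let users calibrate to
their own targets.

```{r calib}
state_service_mixes("Kaduna")$child |> round(3)
```

## What the synthetic generator emulates — and what it does not

`generate_facility_ledgers()` emulates one facility-year per facility:
monthly attendance by group (mean × mean-one lognormal noise, rounded,
so counts are nonnegative and exact at `noise_cv = 0`), drug dispensing
priced from a jittered price list with quantities driven by the service
mixes, and personnel/overhead/capital totals sized so that the costing
pipeline recovers the configured per-visit unit costs — exactly in the
noiseless case (the totals are scaled by the realized post-rounding
utilization weight), and in expectation under noise.
`generate_state_bundle()` presets the generator to a study state's
published weight, visit volumes, component unit costs and calibrated
mixes, so the full loop — generate registers, re-estimate prices and
mixes from them (`estimate_from_ledgers()`), recompute package costs —
lands on the published values up to sampling noise (about 1% relative
standard error at the default 50 facilities and `noise_cv = 0.1`).

The generator does *not* simulate patient-level episodes, seasonality,
facility-size heterogeneity beyond the common noise term, price
correlation across facilities, or reporting gaps. Passing tests
therefore show that the pipeline's arithmetic is right and its
estimators are consistent under well-behaved noise — not that real
facility registers, with their missingness and inconsistencies, would
be handled gracefully.

## Numerical choices and degenerate inputs

- Half-up (commercial) rounding at display only, implemented as
  half-away-from-zero; internal chains are never rounded.
- Zero total visits, zero unit cost or zero available revenue raise
  degenerate-input errors rather than returning Inf/NaN.
- `annualize_capital()` uses the straight-line form at exactly r = 0;
  the annuity factor is continuous there (checked to 1e-6 at r = 1e-9).
- Ties in the child-mix active-set solver cannot occur for the shipped
  price vectors; the solver drops the most negative coordinate, which
  is deterministic.
- Problem sizes: the full test grid is 4 scenarios × 3 states × 4
  groups plus 50-facility synthetic runs; everything completes in a few
  seconds on one CPU.

## Known limitations

- A single growth rate per state; no cohort-component projection,
  migration or age structure.
- No uncertainty intervals: the sensitivity analysis is scenario
  enumeration, as in the source assessment.
- No inflation adjustment: all Naira amounts are 2015 levels, and the
  US$ column is a fixed-rate display conversion.
- Niger's published all-components package costs are inconsistent with
  its published per-visit component costs (Imo and Kaduna reconcile to
  within 0.4 ₦); the package carries the published package costs and
  uses them only in scenario-3 sign checks.
- The scenario-1b/1e "NPHCDA for drugs only" earmark is treated as a
  plain revenue fraction; no separate earmark accounting.

## Worked example

```{r example}
fit <- run_feasibility()
glance(fit)
tidy(fit) |>
  filter(scenario_id == "1a", group == "all_mch") |>
  transmute(state, unit_cost = round_half_up(unit_cost),
            targets, gap = round_half_up(gap))
```

Under scenario 1a (drugs-only package funded by the NHIS half of the
BHCPF) every state shows a multi-hundred-million Naira shortfall for
the combined MCH target; the `r round(glance(fit)$min_crf_percent, 2)`%
minimum-CRF solve says the CRF allocation would need to reach at least
4% before the NHIS route alone covers the largest state's requirement.
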