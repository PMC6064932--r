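#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy a feasibility analysis
#'
#' @param x An `mch_feasibility` object from [run_feasibility()].
#' @param ... Unused.
#' @return The rows tibble: one row per (scenario, state, group) with
#'   unit cost, targets, required, available, lives covered, gap and
#'   additional-funding percentage (all unrounded).
#' @method tidy mch_feasibility
#' @export
tidy.mch_feasibility <- function(x, ...) {
  x$rows
}

#' One-row summary of a feasibility analysis
#'
#' @inheritParams tidy.mch_feasibility
#' @return A one-row tibble: counts of rows and shortfalls, the worst
#'   gap, the largest required amount, and the continuous minimum
#'   percent of the CRF (at the NHIS 50% allocation) that would cover
#'   it.
#' @method glance mch_feasibility
#' @export
glance.mch_feasibility <- function(x, ...) {
  rows <- x$rows
  max_req <- max(rows$required)
  tibble::tibble(
    n_rows = nrow(rows),
    n_shortfall = sum(rows$gap < 0),
    worst_gap = min(rows$gap),
    max_required = max_req,
    min_crf_percent = minimum_crf_percent(max_req, x$alloc)$minimum_percent
  )
}

#' Report layout options
#'
#' @param scenarios,states,groups Nonempty subsets to render; `NULL`
#'   keeps everything present in the rows.
#' @param currency_display `"naira"` or `"naira_plus_usd"` (unit-cost
#'   column shows the US$ equivalent in parentheses).
#' @param rounding_mode `"half_up"` (default) or `"floor"` for displayed
#'   Naira amounts.
#' @param exchange_rate Naira per US$ used at render time.
#' @return A list of class `report_spec`.
#' @export
report_spec <- function(scenarios = NULL, states = NULL, groups = NULL,
                        currency_display = c("naira_plus_usd", "naira"),
                        rounding_mode = c("half_up", "floor"),
                        exchange_rate = 305.5) {
  structure(
    list(scenarios = scenarios, states = states, groups = groups,
         currency_display = match.arg(currency_display),
         rounding_mode = match.arg(rounding_mode),
         exchange_rate = exchange_rate),
    class = "report_spec"
  )
}

group_banner <- c(maternal = "MATERNAL", child = "CHILD",
                  all_mch = "ALL MCH",
                  all_mch_vulnerable = "ALL MCH VULNERABLE GROUP")

#' Render feasibility rows as a publication-style table
#'
#' Reproduces the layout of the published scenario tables: beneficiary
#' groups as banner rows (MATERNAL, CHILD, ALL MCH, ALL MCH VULNERABLE
#' GROUP), the unit cost with its US$ equivalent in parentheses,
#' thousands separators and signed gaps.
#'
#' @param rows A feasibility rows tibble ([tidy()] of a
#'   [run_feasibility()] result), typically one scenario.
#' @param spec A [report_spec()].
#' @return A character vector of table lines (one per row), invisibly
#'   printable with `cat(x, sep = "\n")`.
#' @export
render_feasibility_table <- function(rows, spec = report_spec()) {
  rows <- tibble::as_tibble(rows)
  if (!nrow(rows)) abort_degenerate("`rows` must be nonempty.")
  for (f in c("scenarios", "states", "groups")) {
    keep <- spec[[f]]
    if (!is.null(keep)) {
      col <- c(scenarios = "scenario_id", states = "state",
               groups = "group")[[f]]
      rows <- rows[rows[[col]] %in% keep, ]
    }
  }
  if (!nrow(rows)) abort_degenerate("Report spec selects no rows.")
  disp <- if (spec$rounding_mode == "half_up") round_half_up else floor
  unit_col <- if (spec$currency_display == "naira_plus_usd") {
    sprintf("%s (%.1f)", format_naira(rows$unit_cost),
            round_half_up(to_usd(rows$unit_cost, spec$exchange_rate), 1))
  } else {
    format_naira(rows$unit_cost)
  }
  body <- tibble::tibble(
    group = rows$group,
    State = rows$state,
    `Unit cost of benefit package Naira (US$)` = unit_col,
    `Target beneficiaries` = format_naira(rows$targets),
    `Amount required/year Naira` = formatC(disp(rows$required),
                                           format = "f", digits = 0,
                                           big.mark = ","),
    `Amount available in 2015 Naira` = formatC(disp(rows$available),
                                               format = "f", digits = 0,
                                               big.mark = ","),
    `Lives covered` = format_naira(rows$lives_covered),
    `Gap/Surplus Naira` = formatC(disp(rows$gap), format = "f", digits = 0,
                                  big.mark = ","),
    `Additional aggregate fund needed(%)` = formatC(
      round_half_up(rows$additional_pct), format = "f", digits = 0)
  )
  header <- paste(names(body)[-1], collapse = "\t")
  lines <- character()
  for (scn in unique(rows$scenario_id)) {
    lines <- c(lines, sprintf("Scenario: %s", scn), header)
    sub <- body[rows$scenario_id == scn, ]
    for (g in intersect(names(group_banner), unique(sub$group))) {
      lines <- c(lines, group_banner[[g]])
      blk <- sub[sub$group == g, -1]
      lines <- c(lines, apply(blk, 1, paste, collapse = "\t"))
    }
  }
  unname(lines)
}

#' Write and read machine-readable feasibility results
#'
#' Long-format CSV keyed by (scenario_id, state, group) carrying every
#' numeric field at full precision; reading back recovers the numbers
#' exactly.
#'
#' @param rows A feasibility rows tibble.
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_feasibility_results <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path)
  invisible(path)
}

#' @rdname write_feasibility_results
#' @export
read_feasibility_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Funding gap plot
#'
#' Bar chart of gap/surplus by state, faceted by beneficiary group and
#' scenario; shortfalls point down.
#'
#' @param rows A feasibility rows tibble.
#' @return A ggplot object.
#' @export
plot_funding_gap <- function(rows) {
  rows <- tibble::as_tibble(rows)
  ggplot2::ggplot(rows,
                  ggplot2::aes(x = .data$state, y = .data$gap / 1e9,
                               fill = .data$gap >= 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(group ~ scenario_id) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#d95f02")) +
    ggplot2::labs(x = NULL, y = "Gap / surplus (billion Naira)",
                  title = "Funding gap by state, group and scenario") +
    ggplot2::theme_minimal()
}

#' Lives-covered plot
#'
#' Lives covered against target beneficiaries by scenario.
#'
#' @param rows A feasibility rows tibble.
#' @return A ggplot object.
#' @export
plot_lives_covered <- function(rows) {
  rows <- tibble::as_tibble(rows)
  long <- tidyr::pivot_longer(
    rows, c("lives_covered", "targets"),
    names_to = "measure", values_to = "persons"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$state, y = .data$persons / 1e6,
                               fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(group ~ scenario_id) +
    ggplot2::labs(x = NULL, y = "Persons (millions)", fill = NULL,
                  title = "Lives covered vs target beneficiaries") +
    ggplot2::theme_minimal()
}

#' @rdname plot_funding_gap
#' @param object An `mch_feasibility` object.
#' @param ... Unused.
#' @method autoplot mch_feasibility
#' @export
autoplot.mch_feasibility <- function(object, ...) {
  plot_funding_gap(object$rows)
}

#' Run the full pipeline from a configuration file
#'
#' Executes demography, costing, revenue, feasibility and reporting in
#' one call and writes the artifacts to disk: the long-format results
#' CSV, one rendered table per scenario, and a log of the intermediate
#' aggregates. Any stage failure raises an error naming the stage.
#'
#' @param config A YAML file path or an equivalent named list with
#'   optional entries `states` (path to a state-profile CSV; default the
#'   built-in study states), `scenarios` (character vector, default
#'   `c("1a","1c","1d","1f")`), `groups`, `vulnerable_fraction`,
#'   `exchange_rate`, `rounding_mode`, `counterpart_rate` overrides.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the `mch_feasibility` object.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "mchfundr_pipeline_error")
    })
  }
  cfg <- stage("config", {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    config
  })
  states <- stage("demography", {
    st <- if (!is.null(cfg$states)) read_state_profiles(cfg$states)
          else study_state_profiles()
    if (!nrow(st)) abort_config("Empty state list.")
    st
  })
  dparams <- stage("demography", demography_params(
    vulnerable_fraction = cfg$vulnerable_fraction %||% 0.63))
  cparams <- stage("costing", costing_params(
    exchange_rate = cfg$exchange_rate %||% 305.5))
  fit <- stage("feasibility", run_feasibility(
    states = states,
    scenario_ids = cfg$scenarios %||% c("1a", "1c", "1d", "1f"),
    groups = cfg$groups %||% c("maternal", "child", "all_mch",
                               "all_mch_vulnerable"),
    unit_costs = study_unit_costs(params = cparams),
    demog_params = dparams, params = cparams
  ))
  stage("report", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feasibility_results(fit$rows, file.path(out_dir, "results.csv"))
    rs <- report_spec(rounding_mode = cfg$rounding_mode %||% "half_up",
                      exchange_rate = cparams$exchange_rate)
    writeLines(render_feasibility_table(fit$rows, rs),
               file.path(out_dir, "tables.txt"))
    g <- glance(fit)
    writeLines(c(
      sprintf("states: %s", paste(states$state, collapse = ", ")),
      sprintf("scenarios: %s", paste(fit$scenario_ids, collapse = ", ")),
      sprintf("rows: %d, shortfalls: %d", g$n_rows, g$n_shortfall),
      sprintf("max required: %s Naira", format_naira(g$max_required)),
      sprintf("minimum CRF percent (NHIS 50%% route): %.2f",
              g$min_crf_percent)
    ), file.path(out_dir, "run_log.txt"))
  })
  invisible(fit)
}
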