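# Presentation surfaces: the annual/cumulative funding-and-exclusions table,
# scenario range statistics, and shares of total funding. Aggregation is
# exact in cents; rounding to thousands happens only at presentation.

report_measures <- c("total_funding", "sub_awards", "ec_capital",
                     "ec_vehicles", "ec_lab", "ec_arv", "total_nec")

#' Build the annual report
#'
#' Aggregates cost cells and scenario results into the standard presentation
#' table: one row per measure (total funding, sub-award exclusion, the four
#' other exclusions, total NEC, then one row per scenario's indirect-cost
#' estimate), one column per year plus a `Total` column, in thousands of USD
#' (half-even rounding at presentation only). Exact cent-level aggregates are
#' kept in the `cents` element; per-scenario shares of total funding in the
#' `shares` element.
#'
#' @param cells Cells from [compute_nec()].
#' @param scenario_results Long tibble from [run_scenarios()].
#' @return Object of class `cop_report`: list with `annual` (thousands),
#'   `shares` (percent, two decimals) and `cents` (exact) tibbles.
#' @export
build_report <- function(cells, scenario_results = NULL) {
  years <- sort(unique(cells$year))
  if (!nrow(cells)) {
    cents_wide <- tibble(measure = report_measures, Total = 0)
    return(structure(list(annual = cents_wide, shares = NULL,
                          cents = cents_wide, years = integer()),
                     class = "cop_report"))
  }
  base_long <- cells |>
    group_by(.data$year) |>
    summarise(
      total_funding = sum(.data$total_cents),
      sub_awards = sum(.data$sub_cents),
      ec_capital = sum(.data$ec_capital_cents),
      ec_vehicles = sum(.data$ec_vehicles_cents),
      ec_lab = sum(.data$ec_lab_cents),
      ec_arv = sum(.data$ec_arv_cents),
      total_nec = sum(.data$nec_cents),
      .groups = "drop"
    ) |>
    pivot_longer(-"year", names_to = "measure", values_to = "cents")
  scen_long <- NULL
  if (!is.null(scenario_results) && nrow(scenario_results)) {
    scen_long <- scenario_results |>
      group_by(measure = .data$scenario, .data$year) |>
      summarise(cents = sum(.data$ind_cents), .groups = "drop")
  }
  long <- bind_rows(base_long, scen_long)
  measure_order <- c(report_measures,
                     if (!is.null(scen_long)) unique(scenario_results$scenario))
  long <- long |>
    mutate(measure = factor(.data$measure, levels = measure_order)) |>
    arrange(.data$measure, .data$year)
  totals <- long |>
    group_by(.data$measure) |>
    summarise(cents = sum(.data$cents), .groups = "drop") |>
    mutate(year = "Total")
  cents_wide <- bind_rows(long |> mutate(year = as.character(.data$year)),
                          totals) |>
    pivot_wider(names_from = "year", values_from = "cents",
                values_fill = 0) |>
    arrange(.data$measure) |>
    mutate(measure = as.character(.data$measure))
  annual <- cents_wide |>
    mutate(across(-"measure", ~ round(cents_to_thousands(.x))))
  fund_total <- totals$cents[totals$measure == "total_funding"]
  shares <- NULL
  if (!is.null(scen_long) && length(fund_total) && fund_total > 0) {
    shares <- totals |>
      filter(!.data$measure %in% report_measures) |>
      transmute(scenario = as.character(.data$measure),
                share_pct = share_of_total(.data$cents, fund_total))
  }
  structure(list(annual = annual, shares = shares, cents = cents_wide,
                 years = years),
            class = "cop_report")
}

#' @export
print.cop_report <- function(x, ...) {
  cat("Annual report (in '000 USD)\n")
  df <- as.data.frame(x$annual)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, big.mark = ","))
  print(df, row.names = FALSE)
  if (!is.null(x$shares)) {
    cat("\nScenario shares of total funding (%)\n")
    print(as.data.frame(x$shares), row.names = FALSE)
  }
  invisible(x)
}

#' Scenario range per column
#'
#' The spread (maximum minus minimum scenario estimate) of indirect costs per
#' year and cumulatively, with its share of total funding — the headline
#' "range of potentially accrued indirect costs".
#'
#' @param report A [build_report()] object with at least two scenarios.
#' @return Tibble (`column`, `range_thousands`, `share_pct`).
#' @export
range_summary <- function(report) {
  cents <- report$cents
  scen <- cents |> filter(!.data$measure %in% report_measures)
  if (nrow(scen) < 2) {
    warn("fewer than two scenarios in the report; range is 0.")
  }
  cols <- setdiff(names(cents), "measure")
  fund <- cents |> filter(.data$measure == "total_funding")
  tibble(
    column = cols,
    range_thousands = vapply(cols, function(cl) {
      if (!nrow(scen)) return(0)
      round(cents_to_thousands(max(scen[[cl]]) - min(scen[[cl]])))
    }, numeric(1), USE.NAMES = FALSE),
    share_pct = vapply(cols, function(cl) {
      if (!nrow(scen) || fund[[cl]] <= 0) return(0)
      share_of_total(max(scen[[cl]]) - min(scen[[cl]]), fund[[cl]])
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Share of a component in a total, in percent
#'
#' @param component_total,funding_total Amounts in the same unit;
#'   `funding_total` must be positive.
#' @return `100 * component / total`, rounded to two decimals.
#' @export
#' @examples
#' share_of_total(1917972, 22237882) # 8.62
share_of_total <- function(component_total, funding_total) {
  if (any(is.na(funding_total)) || any(funding_total <= 0)) {
    abort("`funding_total` must be positive.",
          class = "copcost_error_zero_total")
  }
  round(100 * component_total / funding_total, 2)
}

#' Write the report artifacts to a directory
#'
#' Emits `report_annual.csv`, `report_shares.csv`, `report_range.csv` and
#' `retention_table.csv`. Rendering is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param report A [build_report()] object.
#' @param rt Optional [build_retention_table()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, rt = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$annual, file.path(dir, "report_annual.csv"))
  if (!is.null(report$shares)) {
    readr::write_csv(report$shares, file.path(dir, "report_shares.csv"))
  }
  readr::write_csv(range_summary(report), file.path(dir, "report_range.csv"))
  if (!is.null(rt)) {
    readr::write_csv(retention_table_tidy(rt),
                     file.path(dir, "retention_table.csv"))
  }
  invisible(dir)
}
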