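# End-to-end estimation: from the five input tables to per-cell indirect
# cost estimates under every scenario, plus the report surfaces.

as_validated <- function(x, kind) {
  if (is.null(x)) return(NULL)
  x <- tibble::as_tibble(x)
  # tables already carrying integer cents have been validated upstream;
  # anything else (raw generator output, unvalidated reads) goes through
  # the validator, which is idempotent on canonical input
  if (kind %in% c("funding", "subawards", "crosscutting") &&
      "amount_cents" %in% names(x)) {
    return(x)
  }
  validate_cop_table(x, kind)
}

#' Estimate indirect costs from a set of input tables
#'
#' Runs the full model: classification and NA allocation, scope restriction
#' to IOs and universities, retention rates (partner-observed with agency and
#' global fallbacks), MTDC exclusions with proportional back-fill, and the
#' rate scenarios. Tables may be passed raw (documented CSV schemas, dollar
#' `amount` column) or already validated.
#'
#' @param funding,subawards,crosscutting,classes,rates The five input tables
#'   (see [cop_schema()]); `crosscutting` may be `NULL` or empty.
#' @param policy An [exclusion_policy()].
#' @param scenarios Named list of [scenario_spec()]s.
#' @param subaward_window Years of observed sub-award data; default the
#'   years present in `subawards`.
#' @param proportion_year Reference year for the international sub-award
#'   proportion; default the first sub-award year.
#' @param subaward_threshold Sub-partner threshold in USD (default 100,000).
#' @param missing_university Passed to [run_scenarios()].
#' @return Object of class `cop_estimate`: list with `cells` (per
#'   partner/agency/year accounting state), `scenarios` (long per-scenario
#'   results), `retention` (the retention table), `report`, `range`,
#'   `excluded_classes`, `na_allocation`.
#' @export
estimate_indirect_costs <- function(funding, subawards, crosscutting,
                                    classes, rates,
                                    policy = exclusion_policy(),
                                    scenarios = default_scenarios(),
                                    subaward_window = NULL,
                                    proportion_year = NULL,
                                    subaward_threshold = 1e5,
                                    missing_university = "io") {
  funding <- as_validated(funding, "funding")
  subawards <- as_validated(subawards, "subawards")
  crosscutting <- as_validated(crosscutting %||%
                                 tibble(mechanism_id = character(),
                                        partner = character(),
                                        agency = character(),
                                        year = integer(),
                                        category = character(),
                                        amount = numeric()),
                               "crosscutting")
  classes <- as_validated(classes, "classes")
  rates <- as_validated(rates, "rates")

  classified <- classify_funding(funding, classes)
  allocated <- allocate_na(classified)
  in_scope <- filter_in_scope(allocated)
  cells <- build_cost_cells(in_scope,
                            lab_budget_code = policy$lab_budget_code,
                            arv_budget_code = policy$arv_budget_code)

  rt <- build_retention_table(cells, subawards, classes,
                              window_years = subaward_window,
                              proportion_year = proportion_year,
                              threshold = subaward_threshold)
  cells <- apply_retention(cells, rt)
  cells <- direct_exclusions(cells, crosscutting, policy)
  cells <- backfill_exclusions(cells, policy)
  cells <- compute_nec(cells)

  scen <- run_scenarios(cells, rates, scenarios,
                        missing_university = missing_university)
  report <- build_report(cells, scen)
  structure(
    list(
      cells = cells,
      scenarios = scen,
      retention = rt,
      report = report,
      range = range_summary(report),
      excluded_classes = attr(in_scope, "excluded_classes"),
      na_allocation = attr(allocated, "na_allocation")
    ),
    class = "cop_estimate"
  )
}

#' Estimate indirect costs straight from CSV files
#'
#' @param funding,subawards,crosscutting,classes,rates Paths to CSVs in the
#'   documented schemas; `crosscutting` may be `NULL`.
#' @param ... Passed to [estimate_indirect_costs()].
#' @return A `cop_estimate` (see [estimate_indirect_costs()]).
#' @export
estimate_indirect_costs_files <- function(funding, subawards, crosscutting,
                                          classes, rates, ...) {
  estimate_indirect_costs(
    funding = read_cop_table(funding, "funding"),
    subawards = read_cop_table(subawards, "subawards"),
    crosscutting = if (is.null(crosscutting)) NULL else
      read_cop_table(crosscutting, "crosscutting"),
    classes = read_cop_table(classes, "classes"),
    rates = read_cop_table(rates, "rates"),
    ...
  )
}

#' @export
print.cop_estimate <- function(x, ...) {
  cat("Indirect cost estimate:", nrow(x$cells), "cells,",
      length(unique(x$scenarios$scenario)), "scenarios\n\n")
  print(x$report)
  rng <- x$range |> filter(.data$column == "Total")
  if (nrow(rng)) {
    cat(sprintf("\nCumulative scenario range: %s thousand USD (%.2f%% of total funding)\n",
                format(rng$range_thousands, big.mark = ","),
                rng$share_pct))
  }
  invisible(x)
}
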