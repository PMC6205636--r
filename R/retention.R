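# Sub-award retention: how much of each award the prime partner keeps, and
# the adjustment for sub-awards that flow onward to other international
# organizations or universities (which charge their own indirect rates on
# them, so that money is treated as retained for rate purposes).

#' Observed partner retention rates over the sub-award window
#'
#' For every (partner, agency) pair that reported sub-awards inside the
#' observation window, the retention rate is
#' `R = (window funding - window sub-awards) / window funding`. Pairs whose
#' sub-awards exceed their funding are clamped to `R = 0` and flagged
#' (`clamped` column) as a data-quality signal; pairs with zero window
#' funding are dropped with a warning (rate undefined).
#'
#' @param cells Cost cells from [build_cost_cells()].
#' @param subawards Sub-award tibble from [read_cop_table()].
#' @param window_years Years with observed sub-award data; default all years
#'   present in `subawards`.
#' @return Tibble (`partner`, `agency`, `funding_cents`, `subaward_cents`,
#'   `retention`, `clamped`).
#' @export
partner_retention <- function(cells, subawards, window_years = NULL) {
  if (is.null(window_years)) window_years <- sort(unique(subawards$year))
  subs <- subawards |>
    filter(.data$year %in% window_years) |>
    group_by(partner = .data$prime_partner, .data$agency) |>
    summarise(subaward_cents = sum(.data$amount_cents), .groups = "drop")
  fund <- cells |>
    filter(.data$year %in% window_years) |>
    group_by(.data$partner, .data$agency) |>
    summarise(funding_cents = sum(.data$total_cents), .groups = "drop")
  obs <- inner_join(subs, fund, by = c("partner", "agency"))
  no_funding <- anti_join(subs, fund, by = c("partner", "agency"))
  if (nrow(no_funding)) {
    warn(paste0(nrow(no_funding), " (partner, agency) pair(s) report ",
                "sub-awards but no in-scope window funding; retention ",
                "undefined, dropped."))
  }
  out <- obs |>
    mutate(
      retention = pmax(0, 1 - .data$subaward_cents / .data$funding_cents),
      clamped = .data$subaward_cents > .data$funding_cents
    )
  if (any(out$clamped)) {
    warn(paste0("sub-awards exceed funding for ",
                sum(out$clamped), " (partner, agency) pair(s); ",
                "retention clamped to 0."))
  }
  out
}

#' Per-agency proportion of sub-award dollars going to international partners
#'
#' Sub-partners are classified from the partner table; a sub-partner whose
#' within-agency total in the reference year does not exceed the threshold,
#' or whose class is unknown, is treated as local. The proportion is then
#' (sub-award dollars to IO/UNIVERSITY sub-partners) / (all sub-award
#' dollars), per agency. The all-agency pooled proportion is attached as
#' attribute `"global_proportion"` and used as the fallback where an agency
#' has no sub-awards in the reference year.
#'
#' @param subawards Sub-award tibble.
#' @param classes Partner classification tibble.
#' @param year Reference year; default the first year present in the data.
#' @param threshold Within-agency award threshold in USD above which a
#'   sub-partner's own class is honoured (default 100,000).
#' @return Tibble (`agency`, `io_proportion`, `subaward_cents`), with the
#'   pooled proportion as attribute `"global_proportion"`.
#' @export
io_subaward_proportion <- function(subawards, classes,
                                   year = NULL, threshold = 1e5) {
  if (is.null(year)) year <- min(subawards$year)
  threshold_cents <- as_cents(threshold)
  lut <- classes |> distinct(.data$partner, .data$class)
  subs <- subawards |>
    filter(.data$year %in% !!year) |>
    group_by(.data$agency, .data$sub_partner) |>
    summarise(amount_cents = sum(.data$amount_cents), .groups = "drop") |>
    left_join(lut, by = c(sub_partner = "partner")) |>
    mutate(
      class = coalesce(.data$class, "NA"),
      international = .data$class %in% c("IO", "UNIVERSITY") &
        .data$amount_cents > threshold_cents
    )
  out <- subs |>
    group_by(.data$agency) |>
    summarise(
      io_proportion = sum(.data$amount_cents[.data$international]) /
        sum(.data$amount_cents),
      subaward_cents = sum(.data$amount_cents),
      .groups = "drop"
    )
  attr(out, "global_proportion") <-
    sum(subs$amount_cents[subs$international]) / sum(subs$amount_cents)
  attr(out, "year") <- year
  out
}

#' Applied retention rate
#'
#' Adjusts a retention rate upward for the share of sub-awarded funds that
#' flows to other international organizations or universities: that share is
#' treated as retained for rate-application purposes, because the
#' sub-awardees charge their own indirect rates on it. The closed form is
#' `R + (1 - R) * p`.
#'
#' @param retention Retention rate(s) in `[0, 1]`.
#' @param io_proportion Proportion(s) in `[0, 1]` of sub-award dollars going
#'   to international sub-awardees.
#' @return Applied retention rate(s), always `>= retention`.
#' @export
#' @examples
#' applied_retention(0.8633, 0.2675) # 0.8999 (to four decimals)
applied_retention <- function(retention, io_proportion) {
  if (any(is.na(retention)) || any(retention < 0) || any(retention > 1)) {
    abort("`retention` must lie in [0, 1].",
          class = "copcost_error_rate_domain")
  }
  if (any(is.na(io_proportion)) || any(io_proportion < 0) ||
      any(io_proportion > 1)) {
    abort("`io_proportion` must lie in [0, 1].",
          class = "copcost_error_rate_domain")
  }
  retention + (1 - retention) * io_proportion
}

#' Agency and global fallback applied-retention rates
#'
#' Agencies' average retention is the funding-weighted mean of observed
#' partner retention rates (weights: window funding), adjusted by the
#' agency's international sub-award proportion. The global applied average is
#' the funding-weighted mean of observed partners' applied rates across all
#' agencies, used for agencies with no observed partners at all.
#'
#' @param partner_rates Output of [partner_retention()].
#' @param io_props Output of [io_subaward_proportion()].
#' @return List with `agency` (tibble: `agency`, `avg_retention`,
#'   `io_proportion`, `applied_avg`), `global_applied`, `global_proportion`.
#' @export
fallback_rates <- function(partner_rates, io_props) {
  if (!nrow(partner_rates)) {
    abort("no partners with observed sub-award data; the retention model cannot run.",
          class = "copcost_error_no_retention_data")
  }
  global_p <- attr(io_props, "global_proportion")
  if (is.null(global_p) || is.na(global_p)) global_p <- 0
  agency <- partner_rates |>
    group_by(.data$agency) |>
    summarise(
      avg_retention = weighted.mean(.data$retention, .data$funding_cents),
      n_partners = n(),
      funding_cents = sum(.data$funding_cents),
      .groups = "drop"
    ) |>
    left_join(io_props |> select("agency", "io_proportion"), by = "agency") |>
    mutate(
      io_proportion = coalesce(.data$io_proportion, global_p),
      applied_avg = applied_retention(.data$avg_retention,
                                      .data$io_proportion)
    )
  partner_applied <- partner_rates |>
    left_join(agency |> select("agency", "io_proportion"), by = "agency") |>
    mutate(applied = applied_retention(.data$retention, .data$io_proportion))
  list(
    agency = agency,
    global_applied = weighted.mean(partner_applied$applied,
                                   partner_applied$funding_cents),
    global_proportion = global_p
  )
}

#' Build the full retention table
#'
#' Combines observed partner rates, agency applied averages and the global
#' applied average into one lookup object. Every (partner, agency) pair the
#' model meets resolves to some applied rate, with provenance
#' `PARTNER_OBSERVED` > `AGENCY_AVERAGE` > `GLOBAL_AVERAGE`.
#'
#' @inheritParams partner_retention
#' @inheritParams io_subaward_proportion
#' @param proportion_year Reference year for the international sub-award
#'   proportion; default the first year in `subawards`.
#' @return Object of class `retention_table`: list with `partner` and
#'   `agency` tibbles, `global_applied`, `global_proportion`,
#'   `window_years`, `proportion_year`.
#' @export
build_retention_table <- function(cells, subawards, classes,
                                  window_years = NULL,
                                  proportion_year = NULL,
                                  threshold = 1e5) {
  if (is.null(window_years)) window_years <- sort(unique(subawards$year))
  if (is.null(proportion_year)) proportion_year <- min(subawards$year)
  pr <- partner_retention(cells, subawards, window_years)
  props <- io_subaward_proportion(subawards, classes,
                                  year = proportion_year,
                                  threshold = threshold)
  fb <- fallback_rates(pr, props)
  partner <- pr |>
    left_join(fb$agency |> select("agency", "io_proportion"), by = "agency") |>
    mutate(
      applied = applied_retention(.data$retention, .data$io_proportion),
      provenance = "PARTNER_OBSERVED"
    )
  structure(
    list(
      partner = partner,
      agency = fb$agency |> mutate(provenance = "AGENCY_AVERAGE"),
      global_applied = fb$global_applied,
      global_proportion = fb$global_proportion,
      window_years = window_years,
      proportion_year = proportion_year
    ),
    class = "retention_table"
  )
}

#' @export
print.retention_table <- function(x, ...) {
  cat("Retention table\n")
  cat("  sub-award window:", paste(range(x$window_years), collapse = "-"),
      "| proportion year:", x$proportion_year, "\n")
  cat("  observed partner rates:", nrow(x$partner), "\n")
  cat("  agency applied averages:\n")
  print(x$agency |> select("agency", "avg_retention", "io_proportion",
                           "applied_avg"), ...)
  cat(sprintf("  global applied average: %.4f\n", x$global_applied))
  invisible(x)
}

#' Flatten a retention table for the audit artifact
#'
#' @param rt A `retention_table`.
#' @return Tibble (`partner`, `agency`, `rate`, `provenance`) with agency
#'   averages as partner `"*"` and the global average as `("*", "*")`.
#' @export
retention_table_tidy <- function(rt) {
  bind_rows(
    rt$partner |> transmute(.data$partner, .data$agency,
                            rate = .data$applied, .data$provenance),
    rt$agency |> transmute(partner = "*", .data$agency,
                           rate = .data$applied_avg, .data$provenance),
    tibble(partner = "*", agency = "*", rate = rt$global_applied,
           provenance = "GLOBAL_AVERAGE")
  )
}

#' Apply retention rates to cost cells
#'
#' Resolves each cell's applied retention rate (partner-observed, else agency
#' average, else global average), then splits the cell total into retained
#' and sub-awarded money: `ret = round(rate * total)` cents,
#' `sub = total - ret`, so `total = sub + ret` holds exactly per cell.
#'
#' @param cells Cost cells from [build_cost_cells()].
#' @param rt Retention table from [build_retention_table()].
#' @return Cells with `applied_rate`, `rate_provenance`, `ret_cents`,
#'   `sub_cents`.
#' @export
apply_retention <- function(cells, rt) {
  out <- cells |>
    left_join(rt$partner |> select("partner", "agency", p_rate = "applied"),
              by = c("partner", "agency")) |>
    left_join(rt$agency |> select("agency", a_rate = "applied_avg"),
              by = "agency") |>
    mutate(
      applied_rate = coalesce(.data$p_rate, .data$a_rate, rt$global_applied),
      rate_provenance = case_when(
        !is.na(.data$p_rate) ~ "PARTNER_OBSERVED",
        !is.na(.data$a_rate) ~ "AGENCY_AVERAGE",
        TRUE ~ "GLOBAL_AVERAGE"
      ),
      ret_cents = round(.data$applied_rate * .data$total_cents),
      sub_cents = .data$total_cents - .data$ret_cents,
      p_rate = NULL, a_rate = NULL
    )
  out
}
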