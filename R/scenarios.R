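# Rate scenarios: assign an indirect-cost rate to every cell and invert the
# non-excludable costs into indirect costs and the MTDC base. Universities
# carry their own negotiated OSA rates (on- or off-campus basis per
# scenario); international organizations, whose negotiated rates are not
# public, receive either the university average or a fixed assumed rate.

#' Define one rate scenario
#'
#' @param id Scenario label (e.g. `"A"`, `"ASSUMED_10"`).
#' @param university_basis `"ON_CAMPUS"` or `"OFF_CAMPUS"`: which OSA rate
#'   universities are assumed to charge.
#' @param io_rate_rule Rate rule for international organizations:
#'   `"UNIV_ON_AVG"` / `"UNIV_OFF_AVG"` (the unweighted average of university
#'   on-/off-campus rates, per year) or `"FIXED"`.
#' @param fixed_rate Fraction in `[0, 1]`, required when
#'   `io_rate_rule = "FIXED"`.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(id,
                          university_basis = c("ON_CAMPUS", "OFF_CAMPUS"),
                          io_rate_rule = c("UNIV_ON_AVG", "UNIV_OFF_AVG",
                                           "FIXED"),
                          fixed_rate = NULL) {
  university_basis <- match.arg(university_basis)
  io_rate_rule <- match.arg(io_rate_rule)
  if (io_rate_rule == "FIXED") {
    if (is.null(fixed_rate) || is.na(fixed_rate) || fixed_rate < 0 ||
        fixed_rate > 1) {
      abort("a FIXED io_rate_rule needs `fixed_rate` in [0, 1].",
            class = "copcost_error_rate_domain")
    }
  } else {
    fixed_rate <- NA_real_
  }
  structure(list(id = id, university_basis = university_basis,
                 io_rate_rule = io_rate_rule, fixed_rate = fixed_rate),
            class = "scenario_spec")
}

#' The six standard rate scenarios
#'
#' A: universities on-campus, IOs the university on-campus average.
#' B: universities off-campus, IOs the university on-campus average.
#' C: universities off-campus, IOs the university off-campus average.
#' ASSUMED_20 / _15 / _10: universities off-campus, IOs a fixed 20 / 15 / 10%
#' (10% being the de minimis rate available without a negotiated agreement).
#'
#' @param assumed Fixed IO rates for the assumed scenarios.
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function(assumed = c(0.20, 0.15, 0.10)) {
  out <- list(
    A = scenario_spec("A", "ON_CAMPUS", "UNIV_ON_AVG"),
    B = scenario_spec("B", "OFF_CAMPUS", "UNIV_ON_AVG"),
    C = scenario_spec("C", "OFF_CAMPUS", "UNIV_OFF_AVG")
  )
  for (a in assumed) {
    id <- paste0("ASSUMED_", round(100 * a))
    out[[id]] <- scenario_spec(id, "OFF_CAMPUS", "FIXED", fixed_rate = a)
  }
  out
}

# One university's basis rate for one year: the entry whose period covers
# the year, else the nearest entry (rates applied retrospectively or
# prospectively), most recent entry winning ties.
univ_rate_one <- function(entries, year, basis) {
  col <- if (basis == "ON_CAMPUS") "on_campus_osa" else "off_campus_osa"
  covering <- entries[entries$period_start <= year &
                        year <= entries$period_end, ]
  if (nrow(covering)) return(covering[[col]][1])
  dist <- ifelse(year < entries$period_start,
                 entries$period_start - year,
                 year - entries$period_end)
  pick <- order(dist, -entries$period_end)[1]
  entries[[col]][pick]
}

#' Look up a university's OSA rate for a year
#'
#' Uses the rate entry whose period covers the year (inclusive bounds); when
#' no period covers it, the nearest entry's rate is applied retrospectively
#' or prospectively, the most recent period winning ties.
#'
#' @param partner Canonical university name(s).
#' @param year Fiscal year(s) (recycled against `partner`).
#' @param basis `"ON_CAMPUS"` or `"OFF_CAMPUS"`.
#' @param rate_table Rates tibble from [read_cop_table()].
#' @return Numeric rate(s). Universities absent from the table raise
#'   `copcost_error_missing_rate`.
#' @export
university_rate <- function(partner, year,
                            basis = c("ON_CAMPUS", "OFF_CAMPUS"),
                            rate_table) {
  basis <- match.arg(basis)
  n <- max(length(partner), length(year))
  partner <- rep_len(partner, n)
  year <- rep_len(year, n)
  split_tbl <- split(rate_table, rate_table$partner)
  vapply(seq_len(n), function(i) {
    entries <- split_tbl[[partner[i]]]
    if (is.null(entries)) {
      abort(paste0("no NICRA rate entry for university: ", partner[i]),
            class = "copcost_error_missing_rate")
    }
    univ_rate_one(entries, year[i], basis)
  }, numeric(1))
}

#' Average university rate applied to international organizations
#'
#' Unweighted mean over the distinct universities in the rate table of their
#' basis rate for the year. Varies by year as rate periods change.
#'
#' @inheritParams university_rate
#' @return A single rate.
#' @export
io_average_rate <- function(rate_table, year,
                            basis = c("ON_CAMPUS", "OFF_CAMPUS")) {
  basis <- match.arg(basis)
  if (is.null(rate_table) || !nrow(rate_table)) {
    abort("empty rate table: cannot compute the university average rate.",
          class = "copcost_error_empty_rate_table")
  }
  universities <- sort(unique(rate_table$partner))
  mean(university_rate(universities, year, basis, rate_table))
}

#' Invert non-excludable costs into indirect costs and the MTDC base
#'
#' Non-excludable costs are the sum of the MTDC base and the indirect costs
#' charged on it, so `ind = nec * r / (1 + r)` and `mtdc = nec - ind`.
#' Amounts are rounded to integer cents, keeping `nec = mtdc + ind` exact;
#' `ind = r * mtdc` then holds to within `(1 + r)/2` of a cent.
#'
#' @param nec_cents Non-excludable costs in integer cents (vector).
#' @param r Indirect cost rate(s), `>= 0` (recycled).
#' @return Tibble (`ind_cents`, `mtdc_cents`).
#' @export
#' @examples
#' indirect_from_nec(1100, 0.10) # ind 100, mtdc 1000
indirect_from_nec <- function(nec_cents, r) {
  if (any(is.na(r)) || any(r < 0)) {
    abort("indirect cost rate must be non-negative.",
          class = "copcost_error_rate_domain")
  }
  if (any(is.na(nec_cents)) || any(nec_cents < 0)) {
    abort("`nec_cents` must be non-negative.",
          class = "copcost_error_bad_amount")
  }
  ind <- round(nec_cents * r / (1 + r))
  tibble(ind_cents = ind, mtdc_cents = nec_cents - ind)
}

#' Run all rate scenarios over the cost cells
#'
#' For each scenario, universities get their own OSA rate on the scenario's
#' basis and international organizations the scenario's IO rule; indirect
#' costs and the MTDC base follow from [indirect_from_nec()]. Universities
#' without any rate entry (typically non-US universities whose agreements
#' are not public) are treated as IOs for rate assignment by default.
#'
#' @param cells Cells from [compute_nec()].
#' @param rate_table University rates tibble.
#' @param scenarios Named list of [scenario_spec()]s
#'   (default [default_scenarios()]).
#' @param missing_university `"io"` (default) to route universities absent
#'   from the rate table through the IO rate rule, `"error"` to fail.
#' @return Long tibble: one row per cell x scenario with `scenario`, `r`,
#'   `nec_cents`, `ind_cents`, `mtdc_cents`.
#' @export
run_scenarios <- function(cells, rate_table,
                          scenarios = default_scenarios(),
                          missing_university = c("io", "error")) {
  missing_university <- match.arg(missing_university)
  has_rates <- !is.null(rate_table) && nrow(rate_table) > 0
  rated_univs <- if (has_rates) unique(rate_table$partner) else character()
  unrated <- cells |>
    filter(.data$class == "UNIVERSITY",
           !.data$partner %in% rated_univs) |>
    distinct(.data$partner)
  if (nrow(unrated) && missing_university == "error") {
    abort(paste0("universities without rate entries: ",
                 paste(unrated$partner, collapse = ", ")),
          class = "copcost_error_missing_rate")
  }
  years <- sort(unique(cells$year))
  avg <- function(basis) {
    setNames(vapply(years, function(t) {
      io_average_rate(rate_table, t, basis)
    }, numeric(1)), years)
  }
  io_avg <- list()
  needs_avg <- any(vapply(scenarios,
                          function(s) s$io_rate_rule != "FIXED", TRUE)) ||
    (nrow(unrated) > 0)
  if (needs_avg) {
    io_avg <- list(ON_CAMPUS = avg("ON_CAMPUS"),
                   OFF_CAMPUS = avg("OFF_CAMPUS"))
  }

  # university rates per (partner, year, basis), joined back per scenario
  univ_cells <- cells |>
    filter(.data$class == "UNIVERSITY", .data$partner %in% rated_univs) |>
    distinct(.data$partner, .data$year)
  univ_rates <- list()
  if (nrow(univ_cells)) {
    univ_rates <- list(
      ON_CAMPUS = univ_cells |>
        mutate(u_rate = university_rate(.data$partner, .data$year,
                                        "ON_CAMPUS", rate_table)),
      OFF_CAMPUS = univ_cells |>
        mutate(u_rate = university_rate(.data$partner, .data$year,
                                        "OFF_CAMPUS", rate_table))
    )
  }

  one_scenario <- function(spec) {
    io_r <- switch(spec$io_rate_rule,
      UNIV_ON_AVG = io_avg$ON_CAMPUS[as.character(cells$year)],
      UNIV_OFF_AVG = io_avg$OFF_CAMPUS[as.character(cells$year)],
      FIXED = rep(spec$fixed_rate, nrow(cells))
    )
    out <- cells |> mutate(r = unname(io_r))
    if (length(univ_rates)) {
      ur <- univ_rates[[spec$university_basis]]
      out <- out |>
        left_join(ur, by = c("partner", "year")) |>
        mutate(r = if_else(!is.na(.data$u_rate), .data$u_rate, .data$r),
               u_rate = NULL)
    }
    inv <- indirect_from_nec(out$nec_cents, out$r)
    out |>
      mutate(scenario = spec$id, ind_cents = inv$ind_cents,
             mtdc_cents = inv$mtdc_cents) |>
      select("partner", "agency", "year", "class", "scenario", "r",
             "nec_cents", "ind_cents", "mtdc_cents")
  }
  scenarios |> map(one_scenario) |> list_rbind()
}
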