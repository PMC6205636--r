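# Excluded costs: money inside the retained amount on which indirect rates
# cannot be charged — capital works, purchased vehicles, laboratory
# equipment (a fixed fraction of the laboratory-infrastructure budget code)
# and ARV drug procurement. Years without source cross-cutting data receive
# proportional back-filled estimates.

#' Exclusion policy
#'
#' All tunables of the exclusion stage. Defaults: capital = the construction
#' and renovation cross-cutting categories; vehicles = purchased motor
#' vehicles; laboratory equipment = 40% of HLAB budget-code funding; ARV
#' procurement = 100% of HTXD budget-code funding. Observed-year windows
#' default to the years actually present in the cross-cutting data; the
#' back-fill pooling level defaults to partner (falling back to agency, then
#' global).
#'
#' @param capital_categories,vehicle_categories Cross-cutting categories
#'   counted as capital / vehicle spending.
#' @param lab_budget_code,arv_budget_code Budget codes for laboratory
#'   infrastructure and ARV drugs.
#' @param lab_fraction Fraction of lab budget-code funding treated as
#'   equipment (default 0.40).
#' @param capital_observed_years,vehicle_observed_years Years with source
#'   cross-cutting data; `NULL` means derive from the data.
#' @param backfill_level `"partner"`, `"agency"` or `"global"` pooling for
#'   back-filled proportions.
#' @return Object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(capital_categories = c("CONSTRUCTION",
                                                    "RENOVATION",
                                                    "CONSTRUCTION_RENOVATION"),
                             vehicle_categories = "MOTOR_VEHICLES_PURCHASED",
                             lab_budget_code = "HLAB",
                             lab_fraction = 0.40,
                             arv_budget_code = "HTXD",
                             capital_observed_years = NULL,
                             vehicle_observed_years = NULL,
                             backfill_level = c("partner", "agency",
                                                "global")) {
  if (is.na(lab_fraction) || lab_fraction < 0 || lab_fraction > 1) {
    abort("`lab_fraction` must lie in [0, 1].",
          class = "copcost_error_rate_domain")
  }
  structure(
    list(
      capital_categories = capital_categories,
      vehicle_categories = vehicle_categories,
      lab_budget_code = lab_budget_code,
      lab_fraction = lab_fraction,
      arv_budget_code = arv_budget_code,
      capital_observed_years = capital_observed_years,
      vehicle_observed_years = vehicle_observed_years,
      backfill_level = match.arg(backfill_level)
    ),
    class = "exclusion_policy"
  )
}

#' @export
print.exclusion_policy <- function(x, ...) {
  cat("Exclusion policy\n")
  cat("  capital categories :", paste(x$capital_categories, collapse = ", "), "\n")
  cat("  vehicle categories :", paste(x$vehicle_categories, collapse = ", "), "\n")
  cat(sprintf("  lab equipment      : %.0f%% of %s\n", 100 * x$lab_fraction,
              x$lab_budget_code))
  cat("  ARV procurement    : 100% of", x$arv_budget_code, "\n")
  cat("  back-fill level    :", x$backfill_level, "\n")
  invisible(x)
}

sum_crosscutting <- function(crosscutting, categories, years) {
  crosscutting |>
    filter(.data$category %in% categories, .data$year %in% years) |>
    group_by(.data$partner, .data$agency, .data$year) |>
    summarise(cc_cents = sum(.data$amount_cents), .groups = "drop")
}

#' Direct (observed-year) excluded costs per cell
#'
#' Capital and vehicle exclusions are the summed matching cross-cutting
#' amounts in their observed windows (zero elsewhere, pending back-fill);
#' laboratory equipment is `lab_fraction` of the cell's lab budget-code
#' funding and ARV procurement the full ARV budget-code funding, in every
#' year.
#'
#' @param cells Cells from [apply_retention()].
#' @param crosscutting Cross-cutting tibble.
#' @param policy An [exclusion_policy()].
#' @return Cells with `ec_capital_cents`, `ec_vehicles_cents`,
#'   `ec_lab_cents`, `ec_arv_cents` and provenance columns
#'   `ec_capital_src`, `ec_vehicles_src` (`"OBSERVED"` inside the windows).
#'   The resolved observed windows are attached as attributes
#'   `"capital_observed_years"` / `"vehicle_observed_years"`.
#' @export
direct_exclusions <- function(cells, crosscutting, policy = exclusion_policy()) {
  cap_years <- policy$capital_observed_years %||%
    sort(unique(crosscutting$year[crosscutting$category %in%
                                    policy$capital_categories]))
  veh_years <- policy$vehicle_observed_years %||%
    sort(unique(crosscutting$year[crosscutting$category %in%
                                    policy$vehicle_categories]))
  cap <- sum_crosscutting(crosscutting, policy$capital_categories, cap_years)
  veh <- sum_crosscutting(crosscutting, policy$vehicle_categories, veh_years)
  out <- cells |>
    left_join(cap |> rename(cap_cents = "cc_cents"),
              by = c("partner", "agency", "year")) |>
    left_join(veh |> rename(veh_cents = "cc_cents"),
              by = c("partner", "agency", "year")) |>
    mutate(
      ec_capital_cents = if_else(.data$year %in% cap_years,
                                 coalesce(.data$cap_cents, 0), 0),
      ec_vehicles_cents = if_else(.data$year %in% veh_years,
                                  coalesce(.data$veh_cents, 0), 0),
      ec_capital_src = if_else(.data$year %in% cap_years, "OBSERVED",
                               NA_character_),
      ec_vehicles_src = if_else(.data$year %in% veh_years, "OBSERVED",
                                NA_character_),
      ec_lab_cents = round(policy$lab_fraction * .data$hlab_cents),
      ec_arv_cents = .data$htxd_cents,
      cap_cents = NULL, veh_cents = NULL
    )
  attr(out, "capital_observed_years") <- cap_years
  attr(out, "vehicle_observed_years") <- veh_years
  out
}

#' Pooled proportion of a cost category within total funding
#'
#' The back-fill rate: summed category amounts divided by summed funding over
#' the observed window. Zero funding yields 0 with a warning.
#'
#' @param category_cents Category amounts (cents) over the observed window.
#' @param funding_cents Matching funding totals (cents).
#' @return A single fraction.
#' @export
#' @examples
#' pooled_proportion(as_cents(c(10, 20)), as_cents(c(1000, 1000))) # 0.015
pooled_proportion <- function(category_cents, funding_cents) {
  fund <- sum(funding_cents)
  if (fund <= 0) {
    warn("zero funding in the observed window; pooled proportion set to 0.")
    return(0)
  }
  sum(category_cents) / fund
}

# Per-partner / per-agency / global pooled fractions for one EC component.
backfill_fractions <- function(cells_ec, ec_col, observed_years) {
  obs <- cells_ec |> filter(.data$year %in% observed_years)
  if (!nrow(obs) || sum(obs$total_cents) == 0) {
    warn(paste0("no observed-window funding for ", ec_col,
                "; back-fill fractions are 0."))
    return(list(partner = tibble(partner = character(),
                                 agency = character(), frac = numeric()),
                agency = tibble(agency = character(), frac = numeric()),
                global = 0))
  }
  list(
    partner = obs |>
      group_by(.data$partner, .data$agency) |>
      summarise(frac = sum(.data[[ec_col]]) / sum(.data$total_cents),
                fund = sum(.data$total_cents), .groups = "drop") |>
      filter(.data$fund > 0) |>
      select(-"fund"),
    agency = obs |>
      group_by(.data$agency) |>
      summarise(frac = sum(.data[[ec_col]]) / sum(.data$total_cents),
                .groups = "drop"),
    global = pooled_proportion(obs[[ec_col]], obs$total_cents)
  )
}

#' Back-fill capital and vehicle exclusions for unobserved years
#'
#' Years outside the observed cross-cutting windows receive
#' `fraction * total_cents`, where the fraction pools observed-window
#' category spending over observed-window funding at the policy's pooling
#' level: partner (with observed-window funding), falling back to agency,
#' then global. Provenance is recorded per cell.
#'
#' @param cells_ec Output of [direct_exclusions()].
#' @param policy The same [exclusion_policy()].
#' @return Cells with back-filled `ec_capital_cents` / `ec_vehicles_cents`
#'   and provenance (`"PARTNER"`, `"AGENCY"`, `"GLOBAL"`) outside the
#'   observed windows.
#' @export
backfill_exclusions <- function(cells_ec, policy = exclusion_policy()) {
  cap_years <- attr(cells_ec, "capital_observed_years") %||%
    policy$capital_observed_years %||% integer()
  veh_years <- attr(cells_ec, "vehicle_observed_years") %||%
    policy$vehicle_observed_years %||% integer()

  fill_one <- function(cells, ec_col, src_col, observed_years) {
    fr <- backfill_fractions(cells, ec_col, observed_years)
    level <- policy$backfill_level
    out <- cells |>
      left_join(fr$partner |> rename(p_frac = "frac"),
                by = c("partner", "agency")) |>
      left_join(fr$agency |> rename(a_frac = "frac"), by = "agency") |>
      mutate(
        frac = case_when(
          level == "partner" ~ coalesce(.data$p_frac, .data$a_frac,
                                        fr$global),
          level == "agency" ~ coalesce(.data$a_frac, fr$global),
          TRUE ~ fr$global
        ),
        frac_src = case_when(
          level == "partner" & !is.na(.data$p_frac) ~ "PARTNER",
          level != "global" & !is.na(.data$a_frac) ~ "AGENCY",
          TRUE ~ "GLOBAL"
        ),
        !!ec_col := if_else(.data$year %in% observed_years,
                            .data[[ec_col]],
                            round(.data$frac * .data$total_cents)),
        !!src_col := if_else(.data$year %in% observed_years,
                             .data[[src_col]], .data$frac_src),
        p_frac = NULL, a_frac = NULL, frac = NULL, frac_src = NULL
      )
    out
  }
  out <- fill_one(cells_ec, "ec_capital_cents", "ec_capital_src", cap_years)
  out <- fill_one(out, "ec_vehicles_cents", "ec_vehicles_src", veh_years)
  attr(out, "capital_observed_years") <- cap_years
  attr(out, "vehicle_observed_years") <- veh_years
  out
}

#' Non-excludable costs per cell
#'
#' `nec = ret - (capital + vehicles + lab + ARV)`. Cells whose exclusions
#' exceed retained funding are clamped: the components are scaled down by
#' largest-remainder apportionment so they sum exactly to `ret` and
#' `nec = 0`; such cells are flagged (`ec_clamped`) and reported — a
#' data-quality signal, not an error.
#'
#' @param cells_ec Output of [backfill_exclusions()] (or
#'   [direct_exclusions()] when every year is observed).
#' @return Cells with `ec_total_cents`, `nec_cents`, `ec_clamped`; the
#'   identity `ret = ec_total + nec` holds exactly per cell.
#' @export
compute_nec <- function(cells_ec) {
  comp <- c("ec_capital_cents", "ec_vehicles_cents", "ec_lab_cents",
            "ec_arv_cents")
  out <- cells_ec |>
    mutate(ec_total_cents = .data$ec_capital_cents +
             .data$ec_vehicles_cents + .data$ec_lab_cents +
             .data$ec_arv_cents,
           ec_clamped = .data$ec_total_cents > .data$ret_cents)
  over <- which(out$ec_clamped)
  if (length(over)) {
    warn(paste0("excluded costs exceed retained funding in ", length(over),
                " cell(s); components scaled to fit (nec = 0)."))
    for (i in over) {
      w <- as.numeric(out[i, comp])
      scaled <- if (sum(w) > 0) {
        apportion_cents(out$ret_cents[i], w)
      } else {
        rep(0, length(comp))
      }
      out[i, comp] <- as.list(scaled)
    }
    out <- out |>
      mutate(ec_total_cents = .data$ec_capital_cents +
               .data$ec_vehicles_cents + .data$ec_lab_cents +
               .data$ec_arv_cents)
  }
  out |> mutate(nec_cents = .data$ret_cents - .data$ec_total_cents)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
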