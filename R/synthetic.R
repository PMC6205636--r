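# Synthetic COP-like ledger generator. Emits the five input tables with a
# known ground truth so every pipeline stage is testable without external
# data, including exact round-trip recovery when everything is observed.
#
# Construction runs in the reverse direction of the estimator: funding cells
# are drawn first, sub-awards and cross-cutting rows are derived from them
# with known rates and fractions, and the ground truth is the accounting
# identity chain evaluated on the full-information (pre-mask) ledger.
# Unawarded ("NA") funding is carved out of every row at a uniform rate, so
# the estimator's proportional stratum allocation inverts the carve.

#' Default synthetic funding agencies
#'
#' Five agencies with target retention rates, international sub-award
#' proportions and funding weights spanning the observed range of real
#' agency behaviour (high-retention small agencies through low-retention
#' service agencies).
#'
#' @return Tibble (`agency`, `retention`, `io_proportion`, `weight`).
#' @export
synthetic_agencies <- function() {
  tibble(
    agency = c("HHS/CDC", "USAID", "Dept of Defense", "HHS/HRSA",
               "Dept of Labor"),
    retention = c(0.86, 0.89, 0.94, 0.69, 0.99),
    io_proportion = c(0.27, 0.28, 0.76, 0.41, 0.00),
    weight = c(0.35, 0.45, 0.05, 0.10, 0.05)
  )
}

#' Configuration for the synthetic ledger generator
#'
#' Defaults mimic the shape of the real planned-funding data: ten fiscal
#' years, sub-awards observed only in the first three, capital cross-cutting
#' categories from the fourth year, vehicles from the seventh, roughly 60% of
#' funding in scope (IOs and universities), a 14% unawarded ("NA") share, and
#' about a third of partners disclosing sub-awards. Amounts are in USD.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param years Study window (fiscal years).
#' @param countries Country names.
#' @param agencies Tibble as [synthetic_agencies()].
#' @param n_io,n_univ,n_local,n_usg Partner counts per class.
#' @param mean_funding Named mean annual funding per partner class (USD).
#' @param funding_sd,year_sd Log-scale spread of partner size and
#'   year-to-year variation.
#' @param retention_sd Partner-level spread around the agency retention
#'   target.
#' @param univ_on_mean,univ_on_sd Mean/spread of university on-campus OSA
#'   rates.
#' @param univ_off_ratio Off-campus rate as a fraction of on-campus.
#' @param hlab_share,htxd_share Budget-code shares of each cell going to
#'   laboratory infrastructure and ARV drugs.
#' @param capital_fraction,vehicle_fraction True capital / vehicle spending
#'   as fractions of cell totals.
#' @param na_share Fraction of every funding row carved out as unawarded
#'   ("NA") money.
#' @param subaward_years,capital_years,vehicle_years Observation masks:
#'   years whose sub-award / capital / vehicle rows are actually emitted.
#' @param subaward_reporting_rate Probability that a (partner, agency) pair
#'   discloses sub-awards at all.
#' @param subaward_threshold Within-agency threshold (USD) above which a
#'   sub-partner's international class is honoured.
#' @param fully_observed If `TRUE`, switch off every observation gap
#'   (masks cover all years, all pairs report, `na_share = 0`): the
#'   configuration under which the estimator reproduces ground truth to the
#'   cent.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             years = 2007:2016,
                             countries = c("Alphaland", "Betastan",
                                           "Gammara"),
                             agencies = synthetic_agencies(),
                             n_io = 20, n_univ = 8, n_local = 22, n_usg = 4,
                             mean_funding = c(IO = 18e6, UNIVERSITY = 11e6,
                                              LOCAL = 9e6, USG = 24e6),
                             funding_sd = 0.8, year_sd = 0.25,
                             retention_sd = 0.05,
                             univ_on_mean = 0.36, univ_on_sd = 0.05,
                             univ_off_ratio = 0.72,
                             hlab_share = 0.043, htxd_share = 0.143,
                             capital_fraction = 0.0085,
                             vehicle_fraction = 0.0053,
                             na_share = 0.1423,
                             subaward_years = 2007:2009,
                             capital_years = 2010:2016,
                             vehicle_years = 2013:2016,
                             subaward_reporting_rate = 0.40,
                             subaward_threshold = 1e5,
                             fully_observed = FALSE) {
  if (fully_observed) {
    subaward_years <- years
    capital_years <- years
    vehicle_years <- years
    subaward_reporting_rate <- 1
    na_share <- 0
  }
  fracs <- c(hlab_share, htxd_share, capital_fraction, vehicle_fraction,
             na_share, subaward_reporting_rate)
  if (any(is.na(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    abort("all configured fractions must lie in [0, 1].",
          class = "copcost_error_infeasible_config")
  }
  if (any(c(n_io, n_univ, n_local, n_usg) < 0) || n_io + n_univ == 0) {
    abort("partner counts must be non-negative with at least one in-scope partner.",
          class = "copcost_error_infeasible_config")
  }
  if (!all(subaward_years %in% years) || !all(capital_years %in% years) ||
      !all(vehicle_years %in% years)) {
    abort("observation masks must lie within the study years.",
          class = "copcost_error_infeasible_config")
  }
  # excluded costs must fit inside the worst-case retained amount
  ec_frac <- 0.4 * hlab_share + htxd_share + capital_fraction +
    vehicle_fraction
  if (ec_frac >= 0.55) {
    abort(paste0("configured exclusion fractions (", round(ec_frac, 3),
                 " of every cell) cannot fit inside retained funding."),
          class = "copcost_error_infeasible_config")
  }
  structure(
    list(seed = as.integer(seed), years = years, countries = countries,
         agencies = agencies, n_io = n_io, n_univ = n_univ,
         n_local = n_local, n_usg = n_usg, mean_funding = mean_funding,
         funding_sd = funding_sd, year_sd = year_sd,
         retention_sd = retention_sd, univ_on_mean = univ_on_mean,
         univ_on_sd = univ_on_sd, univ_off_ratio = univ_off_ratio,
         hlab_share = hlab_share, htxd_share = htxd_share,
         capital_fraction = capital_fraction,
         vehicle_fraction = vehicle_fraction, na_share = na_share,
         subaward_years = subaward_years, capital_years = capital_years,
         vehicle_years = vehicle_years,
         subaward_reporting_rate = subaward_reporting_rate,
         subaward_threshold = subaward_threshold),
    class = "synthetic_config"
  )
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic COP-like ledger with ground truth
#'
#' @param config A [synthetic_config()].
#' @return Object of class `cop_synthetic`: list with the five raw input
#'   tables (`funding`, `subawards`, `crosscutting`, `classes`, `rates`, in
#'   the documented CSV schemas with dollar `amount` columns), the
#'   `ground_truth` (list of `cells` and `scenarios` tibbles in integer
#'   cents, canonical names), and `config`. Identical configs (same seed)
#'   produce identical output.
#' @export
generate_cop_ledger <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().",
          class = "copcost_error_infeasible_config")
  }
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  years <- cfg$years
  ag <- cfg$agencies

  partners <- tibble(
    raw = c(sprintf("Intl Health Partner %02d", seq_len(cfg$n_io)),
            sprintf("University of Region %02d", seq_len(cfg$n_univ)),
            sprintf("Local Partner %02d", seq_len(cfg$n_local)),
            sprintf("USG Entity %02d", seq_len(cfg$n_usg))),
    class = rep(c("IO", "UNIVERSITY", "LOCAL", "USG"),
                times = c(cfg$n_io, cfg$n_univ, cfg$n_local, cfg$n_usg)),
    org_type = rep(c("International NGO", "University", "Local NGO",
                     "USG Agency"),
                   times = c(cfg$n_io, cfg$n_univ, cfg$n_local, cfg$n_usg))
  )
  partners$partner <- normalize_name(partners$raw)

  # --- partner attributes: agencies, countries, size, budget-code mix -----
  pa <- vector("list", nrow(partners))
  mech_counter <- 0L
  for (k in seq_len(nrow(partners))) {
    n_ag <- sample(1:2, 1, prob = c(0.6, 0.4))
    agencies_k <- sample(ag$agency, min(n_ag, nrow(ag)), prob = ag$weight)
    share <- runif(length(agencies_k))
    n_co <- sample(1:2, 1, prob = c(0.5, 0.5))
    countries_k <- sample(cfg$countries, min(n_co, length(cfg$countries)))
    co_w <- runif(length(countries_k)) + 0.2
    base <- rlnorm(1, log(cfg$mean_funding[[partners$class[k]]]),
                   cfg$funding_sd)
    gw <- runif(4) + 0.1
    code_w <- c(cfg$hlab_share, cfg$htxd_share,
                (1 - cfg$hlab_share - cfg$htxd_share) * gw / sum(gw))
    pa[[k]] <- tibble(
      raw = partners$raw[k], partner = partners$partner[k],
      class = partners$class[k], org_type = partners$org_type[k],
      agency = agencies_k, agency_share = share / sum(share),
      countries = list(countries_k), country_w = list(co_w),
      code_w = list(code_w)
    )
  }
  pa <- list_rbind(pa)
  pa$mechanism_id <- sprintf("M%04d", seq_len(nrow(pa)))
  budget_codes <- c("HLAB", "HTXD", "HVAB", "HBHC", "HTXS", "OHSS")

  # --- per-(partner, agency, year) cell totals and funding rows -----------
  # one persistent base size per (partner, agency), lognormal year wobble
  pa$base <- rlnorm(nrow(pa), log(cfg$mean_funding[pa$class]),
                    cfg$funding_sd) * pa$agency_share
  cells <- pa |>
    cross_join(tibble(year = years)) |>
    mutate(total_cents = as_cents(.data$base * rlnorm(n(), 0, cfg$year_sd)))

  funding_rows <- vector("list", nrow(cells))
  hlab_cell <- numeric(nrow(cells))
  htxd_cell <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    co <- cells$countries[[k]]
    co_split <- apportion_cents(cells$total_cents[k], cells$country_w[[k]])
    rows <- vector("list", length(co))
    for (ci in seq_along(co)) {
      code_split <- apportion_cents(co_split[ci], cells$code_w[[k]])
      rows[[ci]] <- tibble(
        country = co[ci], year = cells$year[k],
        mechanism_id = cells$mechanism_id[k], partner = cells$raw[k],
        org_type = cells$org_type[k], agency = cells$agency[k],
        budget_code = budget_codes, amount_cents = code_split
      )
    }
    rows <- list_rbind(rows)
    hlab_cell[k] <- sum(rows$amount_cents[rows$budget_code == "HLAB"])
    htxd_cell[k] <- sum(rows$amount_cents[rows$budget_code == "HTXD"])
    funding_rows[[k]] <- rows
  }
  funding <- list_rbind(funding_rows) |> filter(.data$amount_cents > 0)
  cells$hlab_cents <- hlab_cell
  cells$htxd_cents <- htxd_cell

  # --- NA carve-out: uniform rate per row, pooled per stratum -------------
  if (cfg$na_share > 0) {
    funding <- funding |>
      mutate(na_cents = round(cfg$na_share * .data$amount_cents),
             amount_cents = .data$amount_cents - .data$na_cents)
    na_rows <- funding |>
      filter(.data$na_cents > 0) |>
      group_by(.data$country, .data$year, .data$budget_code, .data$agency) |>
      summarise(amount_cents = sum(.data$na_cents), .groups = "drop") |>
      mutate(mechanism_id = "M0000", partner = "Not Available",
             org_type = "NA")
    funding <- bind_rows(funding |> select(-"na_cents"), na_rows)
  }

  # --- sub-awards: full-information table, then reporting/mask filters ----
  in_scope <- cells |> filter(.data$class %in% c("IO", "UNIVERSITY"))
  pair_keys <- in_scope |> distinct(.data$partner, .data$raw, .data$agency)
  pair_keys <- pair_keys |>
    left_join(ag |> select("agency", "retention", "io_proportion"),
              by = "agency") |>
    mutate(
      R = round(clip(rnorm(n(), .data$retention, cfg$retention_sd),
                     0.55, 0.995), 4),
      reporting = runif(n()) < cfg$subaward_reporting_rate
    )

  sub_pools <- map(seq_len(nrow(ag)), function(i) {
    tibble(
      agency = ag$agency[i],
      sub_raw = c(sprintf("Intl Sub Org %d-%d", i, 1:3),
                  sprintf("Local Sub Org %d-%d", i, 1:6),
                  sprintf("Unregistered Sub %d", i)),
      sub_class = c(rep("IO", 3), rep("LOCAL", 6), NA_character_),
      pool_w = c(runif(3) + 0.3, runif(6) + 0.3, 0.05)
    )
  }) |> list_rbind()
  sub_pools$sub_partner <- normalize_name(sub_pools$sub_raw)

  full_subs_cells <- in_scope |>
    left_join(pair_keys |> select("partner", "agency", "R", "reporting",
                                  "io_proportion"),
              by = c("partner", "agency")) |>
    mutate(sub_total_cents = round((1 - .data$R) * .data$total_cents))

  sub_rows <- vector("list", nrow(full_subs_cells))
  for (k in seq_len(nrow(full_subs_cells))) {
    st <- full_subs_cells$sub_total_cents[k]
    if (st <= 0) next
    pool <- sub_pools[sub_pools$agency == full_subs_cells$agency[k], ]
    io_part <- round(full_subs_cells$io_proportion[k] * st)
    io_pool <- pool[pool$sub_class %in% "IO", ]
    loc_pool <- pool[!pool$sub_class %in% "IO", ]
    amounts <- c(
      if (io_part > 0) apportion_cents(io_part, io_pool$pool_w) else
        rep(0, nrow(io_pool)),
      apportion_cents(st - io_part, loc_pool$pool_w)
    )
    sub_rows[[k]] <- tibble(
      prime_partner = full_subs_cells$raw[k],
      agency = full_subs_cells$agency[k],
      year = full_subs_cells$year[k],
      sub_partner = c(io_pool$sub_raw, loc_pool$sub_raw),
      amount_cents = amounts
    ) |> filter(.data$amount_cents > 0)
  }
  full_subs <- list_rbind(sub_rows)
  reporting_pairs <- pair_keys |> filter(.data$reporting)
  subawards <- full_subs |>
    mutate(prime_canon = normalize_name(.data$prime_partner)) |>
    semi_join(reporting_pairs |> select(partner = "partner", "agency"),
              by = c(prime_canon = "partner", "agency")) |>
    filter(.data$year %in% cfg$subaward_years) |>
    select(-"prime_canon")

  # --- cross-cutting rows -------------------------------------------------
  cc_full <- in_scope |>
    mutate(
      cap_cents = round(cfg$capital_fraction * .data$total_cents),
      veh_cents = round(cfg$vehicle_fraction * .data$total_cents)
    )
  cc_rows <- vector("list", nrow(cc_full))
  for (k in seq_len(nrow(cc_full))) {
    cap_split <- apportion_cents(cc_full$cap_cents[k], c(3, 2))
    cc_rows[[k]] <- tibble(
      mechanism_id = cc_full$mechanism_id[k], partner = cc_full$raw[k],
      agency = cc_full$agency[k], year = cc_full$year[k],
      category = c("CONSTRUCTION", "RENOVATION",
                   "MOTOR_VEHICLES_PURCHASED"),
      amount_cents = c(cap_split, cc_full$veh_cents[k])
    ) |> filter(.data$amount_cents > 0)
  }
  cc_full_rows <- list_rbind(cc_rows)
  crosscutting <- cc_full_rows |>
    filter(
      (.data$category %in% c("CONSTRUCTION", "RENOVATION") &
         .data$year %in% cfg$capital_years) |
        (.data$category == "MOTOR_VEHICLES_PURCHASED" &
           .data$year %in% cfg$vehicle_years)
    )

  # --- university NICRA rates ---------------------------------------------
  univs <- partners |> filter(.data$class == "UNIVERSITY")
  ymid <- years[ceiling(length(years) / 2)]
  rate_rows <- vector("list", nrow(univs))
  truth_rates <- vector("list", nrow(univs))
  for (k in seq_len(nrow(univs))) {
    on1 <- round(clip(rnorm(1, cfg$univ_on_mean, cfg$univ_on_sd),
                      0.20, 0.60), 4)
    off1 <- round(on1 * cfg$univ_off_ratio, 4)
    if (k == nrow(univs) && nrow(univs) > 1) {
      # one university with only a recent agreement: rates applied
      # retrospectively to the earlier years
      rate_rows[[k]] <- tibble(
        partner = univs$raw[k], period_start = ymid + 1,
        period_end = max(years) + 2,
        on_campus_osa = on1, off_campus_osa = off1
      )
      truth_rates[[k]] <- tibble(partner = univs$partner[k], year = years,
                                 on = on1, off = off1)
    } else {
      on2 <- round(clip(on1 + rnorm(1, 0, 0.01), 0.20, 0.60), 4)
      off2 <- round(on2 * cfg$univ_off_ratio, 4)
      rate_rows[[k]] <- tibble(
        partner = univs$raw[k],
        period_start = c(min(years) - 2, ymid + 1),
        period_end = c(ymid, max(years) + 2),
        on_campus_osa = c(on1, on2), off_campus_osa = c(off1, off2)
      )
      truth_rates[[k]] <- tibble(
        partner = univs$partner[k], year = years,
        on = if_else(years <= ymid, on1, on2),
        off = if_else(years <= ymid, off1, off2)
      )
    }
  }
  rates <- list_rbind(rate_rows)
  truth_rates <- list_rbind(truth_rates)

  # --- classes table (sub-partners with unknown class are omitted) --------
  classes <- bind_rows(
    partners |> transmute(partner = .data$raw, class = .data$class),
    sub_pools |>
      filter(!is.na(.data$sub_class)) |>
      distinct(partner = .data$sub_raw, class = .data$sub_class)
  )

  # --- ground truth: identity chain on the full-information ledger --------
  io_sub_canon <- sub_pools$sub_partner[sub_pools$sub_class %in% "IO"]
  gt <- ground_truth_cells(cfg, in_scope, full_subs, cc_full, truth_rates,
                           io_sub_canon)

  structure(
    list(
      funding = funding |>
        mutate(amount = sprintf("%.2f", .data$amount_cents / 100)) |>
        select(all_of(cop_schema("funding"))),
      subawards = subawards |>
        mutate(amount = sprintf("%.2f", .data$amount_cents / 100)) |>
        select(all_of(cop_schema("subawards"))),
      crosscutting = crosscutting |>
        mutate(amount = sprintf("%.2f", .data$amount_cents / 100)) |>
        select(all_of(cop_schema("crosscutting"))),
      classes = classes,
      rates = rates,
      ground_truth = gt,
      config = cfg
    ),
    class = "cop_synthetic"
  )
}

# Ground truth: exact accounting identities on the pre-mask ledger.
ground_truth_cells <- function(cfg, in_scope, full_subs, cc_full,
                               truth_rates, io_sub_canon) {
  # full-information retention per (partner, agency)
  sub_pair <- full_subs |>
    mutate(partner = normalize_name(.data$prime_partner)) |>
    group_by(.data$partner, .data$agency) |>
    summarise(sub_cents = sum(.data$amount_cents), .groups = "drop")
  fund_pair <- in_scope |>
    group_by(.data$partner, .data$agency) |>
    summarise(funding_cents = sum(.data$total_cents), .groups = "drop")
  R_hat <- fund_pair |>
    left_join(sub_pair, by = c("partner", "agency")) |>
    mutate(R = 1 - coalesce(.data$sub_cents, 0) / .data$funding_cents)

  # full-information international sub-award proportion, year 1
  thr <- as_cents(cfg$subaward_threshold)
  y1 <- min(cfg$years)
  io_sub_names <- io_sub_canon
  p_hat <- full_subs |>
    filter(.data$year == y1) |>
    mutate(sub_canon = normalize_name(.data$sub_partner)) |>
    group_by(.data$agency, .data$sub_canon) |>
    summarise(amount_cents = sum(.data$amount_cents), .groups = "drop") |>
    mutate(international = .data$sub_canon %in% io_sub_names &
             .data$amount_cents > thr) |>
    group_by(.data$agency) |>
    summarise(p = sum(.data$amount_cents[.data$international]) /
                sum(.data$amount_cents), .groups = "drop")

  base <- in_scope |>
    select("partner", "agency", "year", "class", "total_cents",
           "hlab_cents", "htxd_cents") |>
    left_join(R_hat |> select("partner", "agency", "R"),
              by = c("partner", "agency")) |>
    left_join(p_hat, by = "agency") |>
    mutate(
      p = coalesce(.data$p, 0),
      applied = applied_retention(.data$R, .data$p),
      ret_cents = round(.data$applied * .data$total_cents),
      sub_cents = .data$total_cents - .data$ret_cents
    ) |>
    left_join(cc_full |> select("partner", "agency", "year", "cap_cents",
                                "veh_cents"),
              by = c("partner", "agency", "year")) |>
    mutate(
      ec_capital_cents = coalesce(.data$cap_cents, 0),
      ec_vehicles_cents = coalesce(.data$veh_cents, 0),
      ec_lab_cents = round(0.4 * .data$hlab_cents),
      ec_arv_cents = .data$htxd_cents,
      nec_cents = .data$ret_cents - .data$ec_capital_cents -
        .data$ec_vehicles_cents - .data$ec_lab_cents - .data$ec_arv_cents
    )
  if (any(base$nec_cents < 0)) {
    abort(paste0("infeasible synthetic configuration: excluded costs ",
                 "exceed retained funding in ",
                 sum(base$nec_cents < 0), " cell(s)."),
          class = "copcost_error_infeasible_config")
  }

  # per-year university-average rates (unweighted over universities)
  io_avg <- truth_rates |>
    arrange(.data$partner) |>
    group_by(.data$year) |>
    summarise(on = mean(.data$on), off = mean(.data$off), .groups = "drop")

  scen <- default_scenarios() |>
    imap(function(spec, id) {
      rates_y <- switch(spec$io_rate_rule,
        UNIV_ON_AVG = setNames(io_avg$on, io_avg$year),
        UNIV_OFF_AVG = setNames(io_avg$off, io_avg$year),
        FIXED = NULL
      )
      out <- base |>
        mutate(r = if (is.null(rates_y)) spec$fixed_rate else
          unname(rates_y[as.character(.data$year)]))
      if (nrow(truth_rates)) {
        ucol <- if (spec$university_basis == "ON_CAMPUS") "on" else "off"
        out <- out |>
          left_join(truth_rates |> select("partner", "year",
                                          u_rate = all_of(ucol)),
                    by = c("partner", "year")) |>
          mutate(r = if_else(.data$class == "UNIVERSITY" &
                               !is.na(.data$u_rate),
                             .data$u_rate, .data$r),
                 u_rate = NULL)
      }
      out |>
        mutate(scenario = id,
               ind_cents = round(.data$nec_cents * .data$r / (1 + .data$r)),
               mtdc_cents = .data$nec_cents - .data$ind_cents) |>
        select("partner", "agency", "year", "scenario", "r", "ind_cents",
               "mtdc_cents")
    }) |>
    list_rbind()

  list(
    cells = base |>
      select("partner", "agency", "year", "class", "total_cents",
             "sub_cents", "ret_cents", "ec_capital_cents",
             "ec_vehicles_cents", "ec_lab_cents", "ec_arv_cents",
             "nec_cents") |>
      arrange(.data$partner, .data$agency, .data$year),
    scenarios = scen |>
      arrange(.data$scenario, .data$partner, .data$agency, .data$year)
  )
}

#' Write a synthetic ledger to CSV files
#'
#' Writes the five input tables plus `ground_truth_cells.csv` and
#' `ground_truth_scenarios.csv` (in cents). Deterministic: same object,
#' byte-identical files.
#'
#' @param sim A [generate_cop_ledger()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cop_ledger <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$funding, file.path(dir, "funding.csv"))
  readr::write_csv(sim$subawards, file.path(dir, "subawards.csv"))
  readr::write_csv(sim$crosscutting, file.path(dir, "crosscutting.csv"))
  readr::write_csv(sim$classes, file.path(dir, "partner_classes.csv"))
  readr::write_csv(sim$rates, file.path(dir, "nicra_rates.csv"))
  readr::write_csv(sim$ground_truth$cells,
                   file.path(dir, "ground_truth_cells.csv"))
  readr::write_csv(sim$ground_truth$scenarios,
                   file.path(dir, "ground_truth_scenarios.csv"))
  invisible(dir)
}

#' Compare pipeline estimates against synthetic ground truth
#'
#' Joins estimated and true cells on (partner, agency, year) — orphan keys on
#' either side are an error listing the offenders — and reports absolute and
#' relative error per quantity: totals, sub-awards, retained funding,
#' excluded costs, NEC, and per-scenario indirect costs.
#'
#' @param estimate A [estimate_indirect_costs()] result.
#' @param ground_truth The `ground_truth` element of a synthetic ledger.
#' @return Tibble (`quantity`, `n_cells`, `max_abs_error_cents`,
#'   `mean_abs_error_cents`, `true_total_cents`, `est_total_cents`,
#'   `rel_error`).
#' @export
recovery_report <- function(estimate, ground_truth) {
  est_cells <- estimate$cells
  gt_cells <- ground_truth$cells
  key <- c("partner", "agency", "year")
  orphans_est <- anti_join(est_cells, gt_cells, by = key)
  orphans_gt <- anti_join(gt_cells, est_cells, by = key)
  if (nrow(orphans_est) || nrow(orphans_gt)) {
    fmt <- function(x) paste(head(
      paste(x$partner, x$agency, x$year, sep = "/"), 5L), collapse = "; ")
    abort(paste0("cell keys do not match ground truth. ",
                 "estimate-only: [", fmt(orphans_est), "] ",
                 "truth-only: [", fmt(orphans_gt), "]"),
          class = "copcost_error_key_mismatch")
  }
  quantities <- c(total = "total_cents", sub = "sub_cents",
                  ret = "ret_cents", ec_capital = "ec_capital_cents",
                  ec_vehicles = "ec_vehicles_cents", ec_lab = "ec_lab_cents",
                  ec_arv = "ec_arv_cents", nec = "nec_cents")
  j <- inner_join(est_cells, gt_cells, by = key,
                  suffix = c("_est", "_true"))
  base_rows <- imap(quantities, function(col, nm) {
    e <- j[[paste0(col, "_est")]]
    t_ <- j[[paste0(col, "_true")]]
    tibble(quantity = nm, n_cells = nrow(j),
           max_abs_error_cents = max(abs(e - t_), 0),
           mean_abs_error_cents = mean(abs(e - t_)),
           true_total_cents = sum(t_), est_total_cents = sum(e),
           rel_error = if (sum(t_) != 0) (sum(e) - sum(t_)) / sum(t_) else 0)
  }) |> list_rbind()

  js <- inner_join(
    estimate$scenarios |>
      select("partner", "agency", "year", "scenario", ind_est = "ind_cents"),
    ground_truth$scenarios |>
      select("partner", "agency", "year", "scenario",
             ind_true = "ind_cents"),
    by = c(key, "scenario")
  )
  scen_rows <- js |>
    group_by(.data$scenario) |>
    summarise(
      quantity = paste0("ind_", first(.data$scenario)),
      n_cells = n(),
      max_abs_error_cents = max(abs(.data$ind_est - .data$ind_true)),
      mean_abs_error_cents = mean(abs(.data$ind_est - .data$ind_true)),
      true_total_cents = sum(.data$ind_true),
      est_total_cents = sum(.data$ind_est),
      rel_error = if (sum(.data$ind_true) != 0) {
        (sum(.data$ind_est) - sum(.data$ind_true)) / sum(.data$ind_true)
      } else 0,
      .groups = "drop"
    ) |>
    select(-"scenario")
  bind_rows(base_rows, scen_rows)
}
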