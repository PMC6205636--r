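# Partner classification, proportional allocation of unawarded ("NA")
# funding, and restriction of the ledger to the in-scope classes
# (international organizations and universities).

#' Tag funding records with their partner class
#'
#' Looks each canonical partner name up in the classification table. Partners
#' absent from the table, and the sentinel partner `"NA"` (funding not yet
#' awarded when the plan was published), are tagged class `"NA"`. Totals are
#' conserved: this adds a column, never drops a row.
#'
#' @param funding Funding tibble from [read_cop_table()].
#' @param classes Classification tibble (`partner`, `class`).
#' @return The funding tibble with a `class` column in
#'   `c("IO", "UNIVERSITY", "LOCAL", "USG", "NA")`.
#' @export
classify_funding <- function(funding, classes) {
  lut <- classes |> distinct(.data$partner, .data$class)
  out <- funding |>
    left_join(lut, by = "partner") |>
    mutate(class = if_else(.data$partner == "NA", "NA",
                           coalesce(.data$class, "NA")))
  out
}

# Allocate the pooled NA cents of one stratum across recipient rows,
# proportional to their classified amounts. Returns the increment vector.
allocate_pool_to <- function(na_cents, weights) {
  apportion_cents(na_cents, weights)
}

#' Allocate unawarded ("NA") funding proportionately within strata
#'
#' Funding tagged `"NA"` exists primarily because not all agreements are
#' awarded by the time annual plans are published. It is redistributed to the
#' classified rows of its stratum in proportion to their amounts, so the
#' allocated money inherits the stratum's partner, agency and class mix. The
#' primary stratum is `(country, year, budget_code)`; a stratum with NA
#' funding but no classified funding escalates to `(country, year)`, then
#' `(year)`. NA funding that no level can absorb is retained as class `"NA"`
#' rows and reported via the `"na_allocation"` attribute.
#'
#' Conservation is exact: allocated + retained NA equals the input grand
#' total to the cent.
#'
#' @param classified Output of [classify_funding()].
#' @return A tibble of the same shape; classified rows carry their share of
#'   NA funding, remaining rows (if any) are unallocatable NA. Attribute
#'   `"na_allocation"` summarizes cents allocated per level and left over.
#' @export
allocate_na <- function(classified) {
  recipients <- classified |> filter(.data$class != "NA")
  pool <- classified |>
    filter(.data$class == "NA") |>
    group_by(.data$country, .data$year, .data$budget_code, .data$agency,
             .data$mechanism_id, .data$org_type) |>
    summarise(amount_cents = sum(.data$amount_cents), .groups = "drop")

  alloc <- rep(0, nrow(recipients))
  levels <- list(c("country", "year", "budget_code"),
                 c("country", "year"),
                 "year")
  level_totals <- setNames(numeric(length(levels)),
                           vapply(levels, paste, "", collapse = "+"))
  pool$remaining <- pool$amount_cents

  for (li in seq_along(levels)) {
    keys <- levels[[li]]
    if (!nrow(pool) || !sum(pool$remaining)) break
    rec_key <- do.call(paste, c(recipients[keys], sep = "\r"))
    pool_grp <- pool |>
      filter(.data$remaining > 0) |>
      group_by(across(all_of(keys))) |>
      summarise(na_cents = sum(.data$remaining), .groups = "drop")
    grp_key <- do.call(paste, c(pool_grp[keys], sep = "\r"))
    for (g in seq_len(nrow(pool_grp))) {
      idx <- which(rec_key == grp_key[g])
      if (!length(idx) || sum(recipients$amount_cents[idx]) == 0) next
      inc <- apportion_cents(pool_grp$na_cents[g],
                             recipients$amount_cents[idx])
      alloc[idx] <- alloc[idx] + inc
      level_totals[li] <- level_totals[li] + pool_grp$na_cents[g]
      pk <- do.call(paste, c(pool[keys], sep = "\r"))
      pool$remaining[pk == grp_key[g]] <- 0
    }
  }

  leftover <- pool |>
    filter(.data$remaining > 0) |>
    transmute(.data$country, .data$year, .data$mechanism_id,
              partner = "NA", .data$org_type, .data$agency,
              .data$budget_code, amount_cents = .data$remaining,
              class = "NA")
  if (nrow(leftover)) {
    warn(paste0("NA funding of ", format(sum(leftover$amount_cents) / 100,
                                         big.mark = ","),
                " USD could not be allocated (no classified funding in any ",
                "fallback stratum); retained as class NA."))
  }
  out <- bind_rows(
    recipients |> mutate(amount_cents = .data$amount_cents + alloc),
    leftover
  )
  attr(out, "na_allocation") <- list(
    allocated_by_level = level_totals,
    unallocated_cents = sum(leftover$amount_cents)
  )
  out
}

#' Restrict the ledger to in-scope classes (IO and UNIVERSITY)
#'
#' USG and local organizations are excluded from the model: USG management
#' costs are out of scope, and local partners rarely hold negotiated rate
#' agreements. Excluded totals are retained on the `"excluded_classes"`
#' attribute for the audit trail.
#'
#' @param allocated Output of [allocate_na()].
#' @return Tibble of in-scope funding rows; attribute `"excluded_classes"`
#'   holds total cents per excluded class.
#' @export
filter_in_scope <- function(allocated) {
  in_scope <- allocated |> filter(.data$class %in% c("IO", "UNIVERSITY"))
  excluded <- allocated |>
    filter(!.data$class %in% c("IO", "UNIVERSITY")) |>
    group_by(.data$class) |>
    summarise(amount_cents = sum(.data$amount_cents), .groups = "drop")
  if (!nrow(in_scope)) {
    warn("no in-scope (IO or UNIVERSITY) funding found.")
  }
  attr(in_scope, "excluded_classes") <- excluded
  in_scope
}

#' Aggregate in-scope funding into per-(partner, agency, year) cost cells
#'
#' The cost cell is the unit of the whole model: one partner, one funding
#' agency, one fiscal year. Budget-code detail needed by the exclusion stage
#' (laboratory infrastructure and ARV budget codes) is carried alongside the
#' cell total.
#'
#' @param in_scope Output of [filter_in_scope()].
#' @param lab_budget_code,arv_budget_code Budget codes whose totals are
#'   tracked per cell (defaults `"HLAB"`, `"HTXD"`).
#' @return Tibble keyed by (`partner`, `agency`, `year`) with `class`,
#'   `total_cents`, `hlab_cents`, `htxd_cents`.
#' @export
build_cost_cells <- function(in_scope, lab_budget_code = "HLAB",
                             arv_budget_code = "HTXD") {
  in_scope |>
    group_by(.data$partner, .data$agency, .data$year, .data$class) |>
    summarise(
      total_cents = sum(.data$amount_cents),
      hlab_cents = sum(.data$amount_cents[.data$budget_code ==
                                            lab_budget_code]),
      htxd_cents = sum(.data$amount_cents[.data$budget_code ==
                                            arv_budget_code]),
      .groups = "drop"
    ) |>
    arrange(.data$partner, .data$agency, .data$year)
}
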