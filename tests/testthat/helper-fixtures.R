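# Shared fixtures. Built in code, cached for the duration of one test run.

# A minimal validated funding tibble (integer cents), one row per call arg.
make_funding <- function(partner, amount_cents,
                         country = "Alphaland", year = 2007L,
                         agency = "USAID", budget_code = "HVAB",
                         org_type = "International NGO",
                         mechanism_id = "M0001") {
  tibble::tibble(
    country = country, year = as.integer(year),
    mechanism_id = mechanism_id, partner = partner,
    org_type = org_type, agency = agency,
    budget_code = budget_code, amount_cents = as.numeric(amount_cents)
  )
}

make_classes <- function(partner, class) {
  tibble::tibble(partner = partner, class = class)
}

# Minimal cost cells carrying the columns the exclusion stage needs.
make_cells <- function(partner, agency, year, total_cents,
                       class = "IO", hlab_cents = 0, htxd_cents = 0,
                       applied_rate = 1) {
  tibble::tibble(
    partner = partner, agency = agency, year = as.integer(year),
    class = class, total_cents = as.numeric(total_cents),
    hlab_cents = hlab_cents,
    htxd_cents = htxd_cents, applied_rate = applied_rate,
    ret_cents = round(applied_rate * total_cents),
    sub_cents = total_cents - round(applied_rate * total_cents)
  )
}

# Fully observed synthetic ledger + its pipeline estimate, shared across
# files (generation is deterministic in the seed).
shared_full_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- copcost::generate_cop_ledger(
        copcost::synthetic_config(seed = 101, fully_observed = TRUE))
    }
    cache
  }
})

shared_full_estimate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_full_sim()
      cache <<- copcost::estimate_indirect_costs(
        sim$funding, sim$subawards, sim$crosscutting, sim$classes,
        sim$rates)
    }
    cache
  }
})

shared_default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- copcost::generate_cop_ledger(
        copcost::synthetic_config(seed = 202))
    }
    cache
  }
})

shared_default_estimate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_default_sim()
      cache <<- suppressWarnings(copcost::estimate_indirect_costs(
        sim$funding, sim$subawards, sim$crosscutting, sim$classes,
        sim$rates))
    }
    cache
  }
})

# The published reference annual totals (thousands of USD), reshaped into a
# cop_report-like object so the reporting operations can run on it.
reference_report <- function() {
  path <- system.file("extdata", "reference_annual_report.csv",
                      package = "copcost")
  ref <- readr::read_csv(path, show_col_types = FALSE)
  cents <- ref
  names(cents) <- sub("^y", "", names(cents))
  names(cents)[names(cents) == "total"] <- "Total"
  for (cl in setdiff(names(cents), "measure")) {
    cents[[cl]] <- cents[[cl]] * 1e5 # thousands -> cents
  }
  structure(list(annual = ref, shares = NULL, cents = cents,
                 years = 2007:2016),
            class = "cop_report")
}

reference_retention <- function() {
  readr::read_csv(system.file("extdata", "reference_agency_retention.csv",
                              package = "copcost"),
                  show_col_types = FALSE)
}
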