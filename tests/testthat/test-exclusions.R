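test_that("direct_exclusions applies the budget-code and cross-cutting rules", {
  cells <- make_cells("p", "USAID", 2010, as_cents(1000),
                      hlab_cents = as_cents(100),
                      htxd_cents = as_cents(250))
  cc <- tibble::tibble(
    mechanism_id = "M1", partner = "p", agency = "USAID", year = 2010L,
    category = c("CONSTRUCTION", "RENOVATION", "MOTOR_VEHICLES_PURCHASED"),
    amount_cents = as_cents(c(30, 20, 15))
  )
  out <- direct_exclusions(cells, cc)
  expect_identical(out$ec_lab_cents, as_cents(40))   # 40% of HLAB
  expect_identical(out$ec_arv_cents, as_cents(250))  # all of HTXD
  expect_identical(out$ec_capital_cents, as_cents(50))
  expect_identical(out$ec_vehicles_cents, as_cents(15))
  expect_identical(out$ec_capital_src, "OBSERVED")
  # no cross-cutting records at all -> zero capital and vehicles
  out2 <- direct_exclusions(cells, cc[0, ])
  expect_identical(out2$ec_capital_cents, 0)
  expect_identical(out2$ec_vehicles_cents, 0)
})

test_that("pooled_proportion is the windowed ratio with guarded degenerate cases", {
  expect_equal(pooled_proportion(as_cents(c(10, 20)), as_cents(c(1000, 1000))),
               0.015)
  expect_equal(pooled_proportion(as_cents(c(0, 0)), as_cents(c(1000, 1000))),
               0)
  expect_equal(pooled_proportion(as_cents(130070), as_cents(15338981)),
               130070 / 15338981)
  expect_warning(p0 <- pooled_proportion(as_cents(5), 0))
  expect_identical(p0, 0)
})

test_that("backfill uses partner fractions with agency and global fallbacks", {
  cells <- dplyr::bind_rows(
    make_cells("p obs", "USAID", 2010, as_cents(1000)),   # observed window
    make_cells("p obs", "USAID", 2007, as_cents(500)),    # to back-fill
    make_cells("p new", "USAID", 2007, as_cents(400)),    # agency fallback
    make_cells("p other", "HHS/CDC", 2007, as_cents(300)) # global fallback
  )
  cc <- tibble::tibble(
    mechanism_id = "M1", partner = "p obs", agency = "USAID", year = 2010L,
    category = "CONSTRUCTION", amount_cents = as_cents(10)
  )
  policy <- exclusion_policy(capital_observed_years = 2010,
                             vehicle_observed_years = 2010)
  out <- backfill_exclusions(direct_exclusions(cells, cc, policy), policy)
  get <- function(p, y) out$ec_capital_cents[out$partner == p &
                                               out$year == y]
  src <- function(p, y) out$ec_capital_src[out$partner == p &
                                             out$year == y]
  # partner fraction 10/1000 = 0.01 applied to the 2007 total of 500
  expect_identical(get("p obs", 2007), as_cents(5))
  expect_identical(src("p obs", 2007), "PARTNER")
  # agency fraction = USAID observed 10/1000 (only p obs observed)
  expect_identical(get("p new", 2007), as_cents(4))
  expect_identical(src("p new", 2007), "AGENCY")
  # global fraction for the agency with no observed-window funding
  expect_identical(get("p other", 2007), as_cents(3))
  expect_identical(src("p other", 2007), "GLOBAL")
})

test_that("backfill is scale-equivariant in unobserved-year totals", {
  base <- dplyr::bind_rows(
    make_cells("p", "USAID", 2010, as_cents(1000)),
    make_cells("p", "USAID", 2007, as_cents(640))
  )
  doubled <- base |>
    dplyr::mutate(across(c(total_cents, ret_cents),
                         ~ ifelse(year == 2007, .x * 2, .x)))
  cc <- tibble::tibble(mechanism_id = "M1", partner = "p", agency = "USAID",
                       year = 2010L, category = "CONSTRUCTION",
                       amount_cents = as_cents(13))
  policy <- exclusion_policy(capital_observed_years = 2010,
                             vehicle_observed_years = 2010)
  run <- function(cells) {
    backfill_exclusions(direct_exclusions(cells, cc, policy), policy) |>
      dplyr::filter(year == 2007) |>
      dplyr::pull(ec_capital_cents)
  }
  expect_lte(abs(run(doubled) - 2 * run(base)), 1) # exact up to one cent
  # all-zero fractions impute zero
  out0 <- backfill_exclusions(direct_exclusions(base, cc[0, ], policy),
                              policy)
  expect_true(all(out0$ec_capital_cents == 0))
})

test_that("compute_nec subtracts exclusions with exact conservation", {
  cells <- make_cells("p", "USAID", 2010, as_cents(1000)) |>
    dplyr::mutate(ec_capital_cents = as_cents(50),
                  ec_vehicles_cents = as_cents(10),
                  ec_lab_cents = as_cents(40),
                  ec_arv_cents = as_cents(250),
                  ec_capital_src = "OBSERVED", ec_vehicles_src = "OBSERVED")
  out <- compute_nec(cells)
  expect_identical(out$nec_cents, as_cents(650))
  expect_identical(out$ret_cents, out$ec_total_cents + out$nec_cents)
  # EC-free cell: nec equals ret
  out2 <- compute_nec(cells |> dplyr::mutate(ec_capital_cents = 0,
                                             ec_vehicles_cents = 0,
                                             ec_lab_cents = 0,
                                             ec_arv_cents = 0))
  expect_identical(out2$nec_cents, out2$ret_cents)
})

test_that("cells whose exclusions exceed retained funding are clamped and flagged", {
  cells <- make_cells("p", "USAID", 2010, as_cents(100),
                      applied_rate = 0.5) |>
    dplyr::mutate(ec_capital_cents = as_cents(40),
                  ec_vehicles_cents = 0,
                  ec_lab_cents = as_cents(20),
                  ec_arv_cents = as_cents(20),
                  ec_capital_src = "OBSERVED", ec_vehicles_src = "OBSERVED")
  expect_warning(out <- compute_nec(cells), "exceed retained")
  expect_true(out$ec_clamped)
  expect_identical(out$nec_cents, 0)
  expect_identical(out$ec_total_cents, out$ret_cents)
  # proportional scaling: components keep their relative sizes
  expect_identical(out$ec_capital_cents, as_cents(25))
})

test_that("aggregate conservation Ret = EC + NEC holds on a full pipeline run", {
  est <- shared_default_estimate()
  cells <- est$cells
  expect_identical(cells$ret_cents, cells$ec_total_cents + cells$nec_cents)
  expect_identical(sum(cells$sub_cents) + sum(cells$ret_cents),
                   sum(cells$total_cents))
})

test_that("pooled fractions recover the generating fractions on synthetic data", {
  sim <- shared_default_sim()
  est <- shared_default_estimate()
  cfg <- sim$config
  obs <- est$cells |> dplyr::filter(year %in% cfg$capital_years)
  frac <- pooled_proportion(obs$ec_capital_cents, obs$total_cents)
  expect_equal(frac, cfg$capital_fraction, tolerance = 0.02)
  obs_v <- est$cells |> dplyr::filter(year %in% cfg$vehicle_years)
  expect_equal(pooled_proportion(obs_v$ec_vehicles_cents, obs_v$total_cents),
               cfg$vehicle_fraction, tolerance = 0.02)
})
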