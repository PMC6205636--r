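test_that("partner_retention computes window rates with clamping", {
  cells <- make_cells(c("p1", "p2", "p3"), "USAID", 2007,
                      total_cents = as_cents(c(1000, 1000, 500)))
  subs <- tibble::tibble(
    prime_partner = c("p1", "p2", "p3"), agency = "USAID", year = 2007L,
    sub_partner = "s1", amount_cents = as_cents(c(165, 0, 600))
  )
  out <- suppressWarnings(partner_retention(cells, subs))
  expect_equal(out$retention[out$partner == "p1"], 0.835)
  expect_equal(out$retention[out$partner == "p2"], 1)
  expect_equal(out$retention[out$partner == "p3"], 0) # clamped
  expect_true(out$clamped[out$partner == "p3"])
  # boundary: sub-awards equal to funding
  subs$amount_cents[3] <- as_cents(500)
  out2 <- partner_retention(cells, subs)
  expect_equal(out2$retention[out2$partner == "p3"], 0)
  expect_false(out2$clamped[out2$partner == "p3"])
})

test_that("io_subaward_proportion applies class and threshold rules", {
  classes <- make_classes(c("int sub", "loc sub", "small int", "uni sub"),
                          c("IO", "LOCAL", "IO", "UNIVERSITY"))
  subs <- tibble::tibble(
    prime_partner = "prime", agency = "USAID", year = 2007L,
    sub_partner = c("int sub", "loc sub"),
    amount_cents = as_cents(c(300000, 700000))
  )
  p <- io_subaward_proportion(subs, classes)
  expect_equal(p$io_proportion, 0.30)
  # an IO sub-partner at or below the threshold is treated as local
  subs2 <- tibble::tibble(
    prime_partner = "prime", agency = "USAID", year = 2007L,
    sub_partner = c("small int", "loc sub"),
    amount_cents = as_cents(c(50000, 50000))
  )
  p2 <- io_subaward_proportion(subs2, classes)
  expect_equal(p2$io_proportion, 0)
  # all sub-awards to universities above threshold
  subs3 <- tibble::tibble(
    prime_partner = "prime", agency = "USAID", year = 2007L,
    sub_partner = "uni sub", amount_cents = as_cents(2e5)
  )
  expect_equal(io_subaward_proportion(subs3, classes)$io_proportion, 1)
  # unknown sub-partners count as local
  subs4 <- tibble::tibble(
    prime_partner = "prime", agency = "USAID", year = 2007L,
    sub_partner = c("int sub", "who knows"),
    amount_cents = as_cents(c(2e5, 2e5))
  )
  expect_equal(io_subaward_proportion(subs4, classes)$io_proportion, 0.5)
})

test_that("applied_retention reproduces published agency rates", {
  # rounded published (R, p) pairs: HHS/CDC, Dept of Defense, HHS/HRSA
  expect_equal(round(applied_retention(0.8633, 0.2675), 4), 0.8999)
  expect_equal(round(applied_retention(0.9397, 0.7636), 4), 0.9857)
  expect_equal(round(applied_retention(0.6851, 0.4090), 4), 0.8139)
  expect_equal(applied_retention(0.77, 0), 0.77)
})

test_that("applied_retention is monotone, bounded and domain-checked", {
  set.seed(9)
  R <- runif(100); p <- runif(100)
  a <- applied_retention(R, p)
  expect_true(all(a >= R - 1e-12))
  expect_true(all(a <= 1 + 1e-12))
  # monotone in both arguments
  eps <- 0.01
  expect_true(all(applied_retention(pmin(R + eps, 1), p) >= a - 1e-12))
  expect_true(all(applied_retention(R, pmin(p + eps, 1)) >= a - 1e-12))
  expect_error(applied_retention(1.2, 0.5),
               class = "copcost_error_rate_domain")
  expect_error(applied_retention(0.5, -0.1),
               class = "copcost_error_rate_domain")
})

test_that("fallback_rates computes funding-weighted agency and global averages", {
  pr <- tibble::tibble(
    partner = c("p1", "p2"), agency = "USAID",
    funding_cents = c(1e6, 1e6), subaward_cents = c(2e5, 1e5),
    retention = c(0.8, 0.9), clamped = FALSE
  )
  props <- tibble::tibble(agency = "USAID", io_proportion = 0,
                          subaward_cents = 3e5)
  attr(props, "global_proportion") <- 0
  fb <- fallback_rates(pr, props)
  expect_equal(fb$agency$applied_avg, 0.85)
  # single observed agency: global equals the agency average
  expect_equal(fb$global_applied, 0.85)
  # unequal weights shift the mean toward the larger partner
  pr$funding_cents <- c(3e6, 1e6)
  fb2 <- fallback_rates(pr, props)
  expect_equal(fb2$agency$applied_avg, 0.825)
  expect_error(fallback_rates(pr[0, ], props),
               class = "copcost_error_no_retention_data")
})

test_that("rate provenance follows partner > agency > global precedence", {
  cells <- make_cells(
    partner = c("obs partner", "other partner", "lone partner"),
    agency = c("USAID", "USAID", "HHS/CDC"),
    year = 2007, total_cents = as_cents(c(1000, 800, 600))
  )
  subs <- tibble::tibble(
    prime_partner = "obs partner", agency = "USAID", year = 2007L,
    sub_partner = "int sub", amount_cents = as_cents(200)
  )
  classes <- make_classes(c("obs partner", "other partner", "lone partner",
                            "int sub"),
                          c("IO", "IO", "IO", "IO"))
  rt <- build_retention_table(cells, subs, classes)
  out <- apply_retention(cells, rt)
  prov <- setNames(out$rate_provenance, out$partner)
  expect_identical(prov[["obs partner"]], "PARTNER_OBSERVED")
  expect_identical(prov[["other partner"]], "AGENCY_AVERAGE")
  expect_identical(prov[["lone partner"]], "GLOBAL_AVERAGE")
  # applied rates are never below the corresponding raw retention
  expect_true(all(rt$partner$applied >= rt$partner$retention - 1e-12))
  expect_true(all(rt$agency$applied_avg >= rt$agency$avg_retention - 1e-12))
})

test_that("apply_retention preserves Total = Sub + Ret exactly per cell", {
  est <- shared_default_estimate()
  cells <- est$cells
  expect_identical(cells$total_cents, cells$sub_cents + cells$ret_cents)
  # Table-2-style arithmetic: rate 0.8999 on 1000.00 splits 899.90 / 100.10
  one <- make_cells("p", "USAID", 2007, as_cents(1000))
  rt <- list(partner = tibble::tibble(partner = "p", agency = "USAID",
                                      applied = 0.8999),
             agency = tibble::tibble(agency = "USAID",
                                     applied_avg = 0.8999),
             global_applied = 0.8999)
  out <- apply_retention(one |> dplyr::select(-ret_cents, -sub_cents,
                                              -applied_rate), rt)
  expect_identical(out$ret_cents, as_cents(899.90))
  expect_identical(out$sub_cents, as_cents(100.10))
})
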