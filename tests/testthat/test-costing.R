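items <- trial_cost_items()

test_that("cost ledger sums reproduce the printed strategy and phase totals", {
  by_strategy <- sum_ledger(items, by = "strategy")
  expect_equal(by_strategy$total_aud[by_strategy$strategy == "education"], 245252)
  expect_equal(by_strategy$total_hours[by_strategy$strategy == "discount"], 2042)
  # dollar items of the discount inventory sum to 358,274 as computed
  # (the printed 358,275 absorbs the half-dollar from the per-arm design split)
  expect_equal(by_strategy$total_aud[by_strategy$strategy == "discount"], 358274)

  by_phase <- sum_ledger(items, by = c("strategy", "phase"))
  expect_equal(by_phase$total_aud[by_phase$strategy == "education" &
                                    by_phase$phase == "design"], 66986)
  expect_equal(by_phase$total_aud[by_phase$strategy == "education" &
                                    by_phase$phase == "implementation"], 178266)

  expect_equal(sum_ledger(items[0, ], by = "strategy")$total_aud, numeric(0))
  expect_error(sum_ledger(dplyr::mutate(items, strategy = "promo")), "promo")
})

test_that("per-arm totals and store averages reproduce the published summary", {
  arm <- arm_cost_summary()
  d <- arm |> dplyr::filter(arm == "discount_only")
  c_ <- arm |> dplyr::filter(arm == "discount_plus_education")
  expect_equal(d$discount_design, 9572)
  expect_equal(d$total_aud, 214918)
  expect_equal(d$per_store_aud, 21492)
  expect_equal(c_$discount_total, 143357)
  expect_equal(c_$education_total, 245252)
  expect_equal(c_$total_aud, 143357 + 245252)  # 388,609
  expect_equal(c_$per_store_aud, 38861)
})

test_that("CPI deflation uses the index ratio and commutes with summation", {
  expect_equal(cpi_deflation_factor(), (104.8 - 99.8) / 104.8)
  # full precision 4.77%; truncated to 1 d.p. it prints as 4.7%
  expect_equal(floor(cpi_deflation_factor() * 1000) / 10, 4.7)
  expect_equal(cpi_deflate(100, 99.8, 99.8), 100)

  # deflated discount-arm cost is the prose's AUD200,000 at 1 significant figure
  defl <- cpi_deflate(214918)
  expect_equal(signif(defl, 1), 200000)

  # deflate-then-sum equals sum-then-deflate
  x <- c(2068, 9641, 221111)
  expect_equal(sum(cpi_deflate(x)), cpi_deflate(sum(x)), tolerance = 1e-9)

  expect_error(cpi_deflate(1, 0, 100), "positive")
})

test_that("treatment cost deltas price case-years with loading and discounting", {
  uc <- tibble::tibble(disease = "ihd", unit_cost_aud2011 = 1000,
                       cost_basis = "per_case_year")
  zero <- tibble::tibble(disease = "ihd", year = 0, delta_case_years = 0,
                         delta_incident_cases = 0, cost_basis = "per_case_year")
  expect_equal(treatment_cost_delta(zero, uc), 0)

  ten <- dplyr::mutate(zero, delta_case_years = 10)
  expect_equal(treatment_cost_delta(ten, uc), 10 * 1000 * 1.19)

  # accrual in later years is discounted at 3%
  later <- dplyr::mutate(ten, year = 2)
  expect_equal(treatment_cost_delta(later, uc), 11900 / 1.03^2, tolerance = 1e-9)

  # incident-case costing basis uses the incident delta
  inc <- tibble::tibble(disease = "colon_cancer", year = 0,
                        delta_case_years = 99, delta_incident_cases = 2,
                        cost_basis = "per_incident_case")
  uc2 <- tibble::tibble(disease = "colon_cancer", unit_cost_aud2011 = 500,
                        cost_basis = "per_incident_case")
  expect_equal(treatment_cost_delta(inc, uc2), 2 * 500 * 1.19)

  expect_error(treatment_cost_delta(ten, uc2), "unit cost")
})

test_that("ICER classification distinguishes dominance from ratios", {
  # costs more, loses health: dominated, no ratio
  dom <- compute_icer(5e5, -21)
  expect_equal(dom$classification, "dominated")
  expect_true(is.na(dom$icer))

  # saves money, gains health: dominant
  expect_equal(compute_icer(-10000, 2)$classification, "dominant")

  # ordinary ratio below the $50,000/DALY threshold
  r <- compute_icer(40000, 1)
  expect_equal(r$classification, "ratio")
  expect_equal(r$icer, 40000)
  expect_true(r$below_threshold)

  # no health effect
  expect_equal(compute_icer(100, 0)$classification, "no_effect")

  # classification invariant to positive rescaling of both axes
  for (k in c(0.5, 3, 1000)) {
    expect_equal(compute_icer(5e5 * k, -21 * k)$classification, "dominated")
    expect_equal(compute_icer(-1e4 * k, 2 * k)$classification, "dominant")
  }
})
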