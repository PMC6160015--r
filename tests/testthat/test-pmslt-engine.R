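test_that("behavioural effects decay exponentially at 50% per annum", {
  expect_equal(decay_effect(3.7, 0), 3.7)
  expect_equal(decay_effect(1, 1), 0.5)
  expect_equal(decay_effect(1, 5), 0.03125)  # little effect beyond 5 years
  expect_equal(decay_effect(2, 0:3, rate = 0.25), 2 * 0.75^(0:3))
  expect_error(decay_effect(1, -1), "non-negative")
  expect_error(decay_effect(1, 1, rate = 1.5), "0, 1")

  # geometric-series bound: total discounted effect-years < 2x year-one effect
  tot <- sum(discount_value(decay_effect(1, 0:100), 0:100))
  expect_lt(tot, 2)
  expect_gt(tot, 1)
})

test_that("banded exposure distributions shift as piecewise-uniform translations", {
  ex <- tibble::tibble(category = c("low", "high"),
                       lower = c(0, 10), upper = c(10, 20),
                       prevalence = c(0.5, 0.5))
  expect_identical(shift_distribution(ex, 0), ex)

  up <- shift_distribution(ex, 10)
  expect_equal(up$prevalence[up$category == "high"], 1)
  expect_equal(sum(up$prevalence), 1, tolerance = 1e-12)

  half <- shift_distribution(ex, 5)
  expect_equal(half$prevalence, c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(sum(half$prevalence), 1, tolerance = 1e-12)

  # conservation holds for arbitrary shifts across multiple strata
  # (shifts beyond the support clamp into the extreme band, with a warning)
  multi <- tidyr::expand_grid(sex = c("f", "m"), ex)
  for (d in c(-30, -3.3, 1.7, 12, 45)) {
    if (abs(d) >= 20) expect_warning(shift_distribution(multi, d), "clamped")
    shifted <- suppressWarnings(shift_distribution(multi, d))
    sums <- shifted |>
      dplyr::group_by(sex) |>
      dplyr::summarise(s = sum(prevalence))
    expect_equal(sums$s, c(1, 1), tolerance = 1e-12)
  }
  low <- suppressWarnings(shift_distribution(ex, -1000))
  expect_equal(low$prevalence[low$category == "low"], 1)
})

test_that("potential impact fraction follows the prevalence-weighted RR formula", {
  before <- tibble::tibble(category = c("a", "b"), prevalence = c(0.5, 0.5))
  rr <- tibble::tibble(category = c("a", "b"), rr = c(1, 2))

  # unchanged exposure and flat RRs both give PIF = 0
  expect_equal(potential_impact_fraction(before, before, rr)$pif, 0)
  rr1 <- dplyr::mutate(rr, rr = 1)
  after <- tibble::tibble(category = c("a", "b"), prevalence = c(0, 1))
  expect_equal(potential_impact_fraction(before, after, rr1)$pif, 0)

  # hand evaluation: (1.5 - 2) / 1.5 = -1/3
  expect_equal(potential_impact_fraction(before, after, rr)$pif, -1 / 3,
               tolerance = 1e-15)

  # multiplicative combination across risk factors
  pifs <- tibble::tibble(risk_factor = c("x", "y"), disease = "d",
                         pif = c(0.2, 0.5))
  expect_equal(combine_pifs(pifs)$pif, 1 - 0.8 * 0.5)

  expect_error(potential_impact_fraction(
    dplyr::mutate(before, prevalence = 0), after, rr), "zero")
})

test_that("three-state disease process matches hand iteration and conserves mass", {
  # i = 0.1, f = r = 0: case fraction 1 - 0.9^2 = 0.19 after two cycles
  r <- run_disease_model(incidence = 0.1, case_fatality = 0, remission = 0,
                         p0 = 0, pif = 0, horizon = 2)
  expect_equal(r$case[r$year == 2], 0.19, tolerance = 1e-12)

  # PIF = 0 throughout: identical to comparator
  a <- run_disease_model(0.05, 0.1, 0, p0 = 0.02, pif = 0, horizon = 30)
  b <- run_disease_model(0.05, 0.1, 0, p0 = 0.02, pif = rep(0, 30), horizon = 30)
  expect_identical(a, b)

  # conservation at every cycle
  expect_true(all(abs(a$well + a$case + a$dead_disease - 1) < 1e-9))

  # worsening exposure (PIF < 0) never lowers prevalence below comparator
  worse <- run_disease_model(0.05, 0.1, 0, p0 = 0.02, pif = -0.4, horizon = 30)
  expect_true(all(worse$prevalence >= a$prevalence - 1e-12))

  # brute-force loop agrees with the vectorised trajectory
  s <- 0.98; c_ <- 0.02; d <- 0
  for (t in 1:30) {
    new <- s * 0.05 * 1.4; dd <- c_ * 0.1
    s <- s - new; c_ <- c_ + new - dd; d <- d + dd
  }
  expect_equal(worse$case[worse$year == 30], c_, tolerance = 1e-12)

  expect_error(run_disease_model(1.5, 0.9, 0.9, p0 = 0.9, pif = -2, horizon = 2),
               "too large")
})

test_that("present-value discounting matches its closed form", {
  expect_equal(discount_value(100, 0), 100)
  expect_equal(discount_value(103, 1), 100)
  expect_equal(round(discount_value(100, 24), 2), 49.19)
})

test_that("null intervention leaves the lifetable unchanged", {
  epi <- tiny_epi()
  res <- run_lifetable(epi, shifts = NULL)
  expect_equal(res$dalys_averted, 0)
  expect_equal(sum(abs(res$case_year_deltas$delta_case_years)), 0)
  expect_equal(sum(abs(res$case_year_deltas$delta_incident_cases)), 0)
  expect_equal(glance(res)$dalys_averted, 0)
})

test_that("harmful exposure shifts with RR > 1 lose health and add disease", {
  epi <- tiny_epi()
  res <- run_lifetable(epi, tibble::tibble(risk_factor = "bmi", delta0 = 2))
  expect_lt(res$dalys_averted, 0)
  cy <- res$case_year_deltas |>
    dplyr::group_by(disease) |>
    dplyr::summarise(d = sum(delta_case_years))
  expect_gt(cy$d, 0)  # more prevalent case-years than the comparator

  # on the full synthetic inputs too, with BMI and sodium both raised
  full <- generate_epi_inputs(seed = 5)
  harm <- run_lifetable(full, tibble::tibble(
    risk_factor = c("bmi", "sodium"), delta0 = c(1.15, 216.67)
  ))
  expect_lt(harm$dalys_averted, 0)
  expect_gt(treatment_cost_delta(harm$case_year_deltas, full$unit_costs), 0)

  # and a beneficial shift gains health
  good <- run_lifetable(full, tibble::tibble(risk_factor = "fruit", delta0 = 30))
  expect_gt(good$dalys_averted, 0)
})

test_that("background trends enter both scenarios so only the intervention drives DALYs", {
  epi <- tiny_epi()
  bg <- tibble::tibble(risk_factor = "bmi", delta0 = 0.5)
  with_bg <- run_lifetable(epi, shifts = NULL, background = bg)
  expect_equal(with_bg$dalys_averted, 0)
  # the background does alter the comparator's health level
  no_bg <- run_lifetable(epi, shifts = NULL)
  expect_lt(with_bg$h_comparator, no_bg$h_comparator)
})

test_that("cohort lifetable agrees with an individual-level microsimulation", {
  epi <- tiny_epi()
  delta0 <- 2
  lt <- run_lifetable(epi, tibble::tibble(risk_factor = "bmi", delta0 = delta0))
  ms <- microsim_oracle(epi, delta0 = delta0, n_sim = 1e5, seed = 99)

  # DALYs averted within 3 Monte Carlo SEs (common random numbers)
  expect_lt(abs(lt$dalys_averted - ms$dalys), 3 * ms$se_dalys)

  # absolute health-adjusted life-year levels agree closely too
  expect_lt(abs(lt$h_comparator - ms$h_comp) / ms$h_comp, 0.005)
  expect_lt(abs(lt$h_intervention - ms$h_int) / ms$h_int, 0.005)
})
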