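test_that("generated epidemiological inputs satisfy all structural invariants", {
  epi <- generate_epi_inputs(seed = 1)
  expect_s3_class(epi, "epi_inputs")
  expect_silent(validate_epi_inputs(epi))

  # prevalence normalisation holds exactly in every stratum
  sums <- epi$exposure |>
    dplyr::group_by(risk_factor, sex, age_lo) |>
    dplyr::summarise(s = sum(prevalence), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # probability bounds
  expect_true(all(epi$mortality$rate >= 0 & epi$mortality$rate <= 1))
  with(epi$disease_epi, {
    expect_true(all(incidence >= 0 & incidence <= 1))
    expect_true(all(case_fatality >= 0 & case_fatality <= 1))
    expect_true(all(prevalence >= 0 & prevalence <= 1))
  })
  expect_true(all(epi$rr$rr >= 0))
})

test_that("generation is deterministic for a fixed seed and varies across seeds", {
  a <- generate_epi_inputs(seed = 1)
  b <- generate_epi_inputs(seed = 1)
  c <- generate_epi_inputs(seed = 2)
  expect_identical(a$mortality, b$mortality)
  expect_identical(a$disease_epi, b$disease_epi)
  expect_identical(a$exposure, b$exposure)
  expect_false(identical(rlang::hash(a$disease_epi), rlang::hash(c$disease_epi)))
})

test_that("unknown disease names are rejected with the offender named", {
  expect_error(generate_epi_inputs(seed = 1, diseases = c("ihd", "gout")),
               "gout")
})

test_that("epi inputs survive a CSV round trip", {
  epi <- generate_epi_inputs(seed = 3)
  dir <- withr::local_tempdir()
  write_epi_inputs(epi, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "mortality.csv", "disease_epi.csv", "exposure.csv", "rr.csv",
    "unit_costs.csv"
  )))))
  back <- read_epi_inputs(dir)
  expect_silent(validate_epi_inputs(back))
  expect_equal(back$mortality$rate, epi$mortality$rate, tolerance = 1e-12)
  expect_equal(back$rr$rr, epi$rr$rr, tolerance = 1e-12)
})

test_that("sales series reproduce configured effects and respect bounds", {
  baseline <- trial_baseline_diet()
  # zero effect: discount mean equals baseline mean within 3 SE
  s0 <- generate_sales_series(baseline, effect = 0, seasonal_amplitude = 0,
                              noise_sd = 0.05, seed = 11)
  expect_true(all(s0$grams >= 0))
  rec0 <- recover_step_effect(s0)
  se <- 0.05 * sqrt(1 / 24 + 1 / 49)  # relative SE of the mean ratio
  expect_true(all(abs(rec0$effect_hat) < 3 * se))

  # injected +11% step on cereals recovered exactly as noise vanishes
  s1 <- generate_sales_series(baseline, effect = c(cereals = 0.11),
                              seasonal_amplitude = 0, noise_sd = 0, seed = 1)
  rec1 <- recover_step_effect(s1)
  expect_equal(rec1$effect_hat[rec1$category == "cereals"], 0.11,
               tolerance = 1e-12)
  expect_equal(max(abs(rec1$effect_hat[rec1$category != "cereals"])), 0)

  # determinism
  expect_identical(
    generate_sales_series(baseline, effect = 0.05, seed = 4),
    generate_sales_series(baseline, effect = 0.05, seed = 4)
  )
  expect_error(generate_sales_series(
    dplyr::mutate(baseline, weight_g = -weight_g)), "non-negative")
})

test_that("step effects recovered through the diet-response stage at low noise", {
  baseline <- trial_baseline_diet()
  eff <- c(cereals = 0.08, fruit_fresh = 0.15, water = -0.05)
  s <- generate_sales_series(baseline, effect = eff, seasonal_amplitude = 0,
                             noise_sd = 0.03, seed = 21)
  rec <- recover_step_effect(s)
  se <- 0.03 * sqrt(1 / 24 + 1 / 49)
  for (cat in names(eff)) {
    expect_lt(abs(rec$effect_hat[rec$category == cat] - eff[[cat]]),
              3 * se * (1 + abs(eff[[cat]])))
  }
})
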