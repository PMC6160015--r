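# Small hand-built epidemiological input set: one disease, one risk factor
# with two exposure bands, single age band, both sexes covered but only a
# three-age female cohort populated. Every rate is chosen so hand iteration
# and the microsimulation oracle are tractable.
tiny_epi <- function(max_age = 70, cohort_ages = 60:62,
                     persons = c(500, 300, 200),
                     incidence = 0.05, case_fatality = 0.1,
                     p0 = 0.05, q_base = 0.02,
                     band_prev = c(0.6, 0.4), band_rr = c(1, 2),
                     yld = 0.1, dw = 0.2) {
  ages <- 0:max_age
  sexes <- c("female", "male")
  mortality <- tidyr::expand_grid(sex = sexes, age = ages) |>
    dplyr::mutate(rate = q_base)
  disease_epi <- tidyr::expand_grid(disease = "ihd", sex = sexes, age = ages) |>
    dplyr::mutate(incidence = incidence, case_fatality = case_fatality,
                  remission = 0, prevalence = p0)
  exposure <- tidyr::expand_grid(
    risk_factor = "bmi", sex = sexes,
    tibble::tibble(age_lo = 18, age_hi = max_age)
  ) |>
    tidyr::expand_grid(tibble::tibble(
      category = c("low", "high"), lower = c(20, 27.5), upper = c(27.5, 35),
      prev = band_prev
    )) |>
    dplyr::rename(prevalence = prev)
  rr <- tibble::tibble(risk_factor = "bmi", disease = "ihd",
                       category = c("low", "high"), rr = band_rr)
  unit_costs <- tibble::tibble(disease = "ihd", disability_weight = dw,
                               unit_cost_aud2011 = 1000,
                               cost_basis = "per_case_year")
  population <- tibble::tibble(age = cohort_ages, sex = "female",
                               persons = persons)
  background_morbidity <- tibble::tibble(age = ages, yld_rate = yld)
  structure(
    list(mortality = mortality, disease_epi = disease_epi,
         exposure = exposure, rr = rr, unit_costs = unit_costs,
         population = population,
         background_morbidity = background_morbidity, seed = NA_integer_),
    class = "epi_inputs"
  )
}

# closed-form PIF for the tiny two-band instance under an upward shift
# delta (piecewise-uniform translation, upper band clamped):
# p1' = p1 (1 - delta/w1), p2' = p2 + p1 delta/w1
tiny_pif <- function(delta, band_prev = c(0.6, 0.4), band_rr = c(1, 2),
                     w1 = 7.5) {
  moved <- band_prev[1] * pmin(1, pmax(0, delta / w1))
  denom <- sum(band_prev * band_rr)
  num <- -moved * (band_rr[2] - band_rr[1])
  num / denom
}
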