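#' Exposure band definitions for the four dietary risk factors
#'
#' Exposure is modelled categorically (bands of the underlying continuous
#' scale) so that potential impact fractions are exact finite sums. Bands are
#' half-open `[lower, upper)` with finite end caps; the reference category
#' (relative risk 1) is the healthiest band: lowest for BMI and sodium,
#' highest for fruit and vegetables.
#'
#' @return Tibble with `risk_factor`, `category`, `lower`, `upper`,
#'   `reference` (logical).
#' @export
exposure_bands <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      risk_factor = "bmi", category = c("bmi_lt25", "bmi_25_30", "bmi_30_35", "bmi_35plus"),
      lower = c(15, 25, 30, 35), upper = c(25, 30, 35, 50),
      reference = c(TRUE, FALSE, FALSE, FALSE)
    ),
    tibble::tibble(
      risk_factor = "sodium", category = c("na_lt1500", "na_1500_2300", "na_2300_3000", "na_3000plus"),
      lower = c(500, 1500, 2300, 3000), upper = c(1500, 2300, 3000, 6000),
      reference = c(TRUE, FALSE, FALSE, FALSE)
    ),
    tibble::tibble(
      risk_factor = "fruit", category = c("fruit_lt40", "fruit_40_80", "fruit_80_120", "fruit_120plus"),
      lower = c(0, 40, 80, 120), upper = c(40, 80, 120, 400),
      reference = c(FALSE, FALSE, FALSE, TRUE)
    ),
    tibble::tibble(
      risk_factor = "vegetable", category = c("veg_lt50", "veg_50_100", "veg_100_150", "veg_150plus"),
      lower = c(0, 50, 100, 150), upper = c(50, 100, 150, 500),
      reference = c(FALSE, FALSE, FALSE, TRUE)
    )
  )
}

adult_age_bands <- function(max_age = 100) {
  tibble::tibble(
    age_lo = c(18, 30, 45, 60, 75),
    age_hi = c(29, 44, 59, 74, max_age)
  )
}

#' Generate a complete synthetic epidemiological input set
#'
#' Builds every input the lifetable pipeline needs — all-cause mortality by
#' single year of age and sex, disease incidence/case-fatality/remission/
#' prevalence schedules, categorical risk-factor exposure prevalence,
#' relative risks, disability weights, unit treatment costs, adult
#' population structure and background (other-cause) disability — with the
#' statistical structure the analysis assumes. Magnitudes are
#' order-of-magnitude plausible for an adult population (e.g. ischaemic
#' heart disease incidence of a few per 1000 person-years rising steeply
#' with age); they are synthetic and make no claim to match any measured
#' population.
#'
#' @param seed Integer seed; the full set is deterministic given the seed.
#' @param n_ages Number of single-year ages starting at 0 (default 101,
#'   i.e. ages 0-100).
#' @param diseases Character vector drawn from [modelled_diseases()].
#' @param n_adults Adult population size; default from [trial_population()].
#' @return An object of class `epi_inputs`: a list with tibbles `mortality`,
#'   `disease_epi`, `exposure`, `rr`, `unit_costs`, `population`,
#'   `background_morbidity`, plus the `seed`.
#' @export
#' @examples
#' epi <- generate_epi_inputs(seed = 1)
#' names(epi)
generate_epi_inputs <- function(seed = 1, n_ages = 101,
                                diseases = modelled_diseases(),
                                n_adults = trial_population()$n_adults) {
  unknown <- setdiff(diseases, modelled_diseases())
  if (length(unknown) > 0) {
    abort(paste0("Unknown disease name(s): ", paste(unknown, collapse = ", "),
                 ". Valid diseases: ", paste(modelled_diseases(), collapse = ", "), "."))
  }
  stopifnot(n_ages >= 2, n_adults > 0)
  max_age <- n_ages - 1
  ages <- 0:max_age
  sexes <- c("female", "male")

  withr::with_seed(seed, {
    # all-cause mortality: Gompertz rise + infant bump, mild noise,
    # forced monotone non-decreasing above age 60
    mortality <- tidyr::expand_grid(sex = sexes, age = ages) |>
      dplyr::mutate(
        base = 0.0004 + 1.2e-5 * exp(0.095 * .data$age) + 0.003 * exp(-.data$age),
        base = .data$base * ifelse(.data$sex == "female", 0.8, 1),
        rate = pmin(0.95, .data$base * rlnorm(dplyr::n(), 0, 0.03))
      ) |>
      dplyr::group_by(.data$sex) |>
      dplyr::mutate(rate = ifelse(.data$age >= 60,
                                  cummax(replace(.data$rate, .data$age < 60, 0)),
                                  .data$rate)) |>
      dplyr::ungroup() |>
      dplyr::select("age", "sex", "rate")

    dpar <- tibble::tibble(
      disease = modelled_diseases(),
      i_max = c(0.020, 0.012, 0.008, 0.015, 0.004),
      a_mid = c(70, 75, 72, 55, 72),
      f0 = c(0.030, 0.050, 0.020, 0.008, 0.100),
      remission = c(0, 0, 0, 0, 0),
      mean_duration = c(8, 6, 10, 20, 5),
      disability_weight = c(0.15, 0.25, 0.10, 0.12, 0.30),
      unit_cost_mean = c(6000, 9000, 4000, 5000, 30000),
      cost_basis = c("per_case_year", "per_case_year", "per_case_year",
                     "per_case_year", "per_incident_case")
    ) |>
      dplyr::filter(.data$disease %in% diseases)

    disease_epi <- tidyr::expand_grid(
      disease = dpar$disease, sex = sexes, age = ages
    ) |>
      dplyr::left_join(dpar, by = "disease") |>
      dplyr::mutate(
        sex_mult = ifelse(.data$sex == "female", 0.85, 1),
        incidence = ifelse(.data$age < 18, 0,
          pmin(0.5, .data$i_max * .data$sex_mult *
                 stats::plogis((.data$age - .data$a_mid) / 8) *
                 rlnorm(dplyr::n(), 0, 0.05))),
        case_fatality = pmin(0.4, .data$f0 * exp(0.035 * pmax(0, .data$age - 50)) *
                               rlnorm(dplyr::n(), 0, 0.05)),
        prevalence = pmin(0.5, .data$incidence * .data$mean_duration)
      ) |>
      dplyr::select("disease", "age", "sex", "incidence", "case_fatality",
                    "remission", "prevalence")

    unit_costs <- dpar |>
      dplyr::mutate(
        unit_cost_aud2011 = round(.data$unit_cost_mean *
                                    rgamma(dplyr::n(), shape = 100, rate = 100))
      ) |>
      dplyr::select("disease", "disability_weight", "unit_cost_aud2011",
                    "cost_basis")

    # categorical exposure prevalence by age band and sex, normalised to 1
    bands <- exposure_bands()
    base_w <- c(0.30, 0.35, 0.22, 0.13)  # loosely: overweight-heavy adult pop
    exposure <- tidyr::expand_grid(
      risk_factor = unique(bands$risk_factor),
      dplyr::select(adult_age_bands(max_age), "age_lo", "age_hi"),
      sex = sexes
    ) |>
      dplyr::left_join(bands, by = "risk_factor",
                       relationship = "many-to-many") |>
      dplyr::group_by(.data$risk_factor, .data$age_lo, .data$age_hi, .data$sex) |>
      dplyr::mutate(
        w = base_w[seq_len(dplyr::n())] * rlnorm(dplyr::n(), 0, 0.15),
        prevalence = .data$w / sum(.data$w)
      ) |>
      dplyr::ungroup() |>
      dplyr::select("risk_factor", "sex", "age_lo", "age_hi",
                    "category", "lower", "upper", "prevalence")

    rr <- generate_relative_risks(dpar$disease)

    population <- tidyr::expand_grid(sex = sexes, age = 18:max_age) |>
      dplyr::mutate(w = exp(-0.025 * (.data$age - 18))) |>
      dplyr::mutate(persons = .data$w / sum(.data$w) * n_adults) |>
      dplyr::select("age", "sex", "persons")

    background_morbidity <- tibble::tibble(
      age = ages,
      yld_rate = pmin(0.45, 0.05 + 0.0015 * pmax(0, ages - 18))
    )
  })

  structure(
    list(
      mortality = mortality, disease_epi = disease_epi, exposure = exposure,
      rr = rr, unit_costs = unit_costs, population = population,
      background_morbidity = background_morbidity, seed = seed
    ),
    class = "epi_inputs"
  )
}

# band-level relative risks; sodium bands derive from a per-100 mg log-linear
# RR evaluated at band midpoints relative to the reference band midpoint
generate_relative_risks <- function(diseases, sodium_rr_per_100mg = 1.012) {
  bands <- exposure_bands()
  mids <- bands |>
    dplyr::mutate(mid = (.data$lower + .data$upper) / 2)

  per_band <- list(
    bmi = c(1, 1.30, 1.70, 2.30),
    fruit = c(1.40, 1.25, 1.10, 1),
    vegetable = c(1.35, 1.20, 1.08, 1)
  )
  affects <- list(
    bmi = c("ihd", "stroke", "diabetes", "hypertensive_heart_disease", "colon_cancer"),
    sodium = c("ihd", "stroke", "hypertensive_heart_disease"),
    fruit = c("ihd", "stroke", "colon_cancer"),
    vegetable = c("ihd", "stroke", "colon_cancer")
  )

  purrr::imap_dfr(affects, function(ds, rf) {
    ds <- intersect(ds, diseases)
    if (length(ds) == 0) return(NULL)
    b <- dplyr::filter(mids, .data$risk_factor == rf)
    purrr::map_dfr(ds, function(d) {
      if (rf == "sodium") {
        ref_mid <- b$mid[b$reference]
        rr <- sodium_rr_per_100mg^((b$mid - ref_mid) / 100)
      } else {
        rr <- per_band[[rf]]
        rr <- rr / rr[b$reference]  # anchor reference at exactly 1
      }
      tibble::tibble(risk_factor = rf, disease = d,
                     category = b$category, rr = rr)
    })
  })
}

#' Validate an epidemiological input set
#'
#' Checks the structural invariants: probabilities in `[0, 1]`, all-cause
#' mortality monotone non-decreasing above age 60, exposure prevalences
#' summing to 1 within each stratum, non-negative relative risks with the
#' reference category at exactly 1.
#'
#' @param epi An `epi_inputs` object.
#' @return `epi`, invisibly; aborts with a message on any violation.
#' @export
validate_epi_inputs <- function(epi) {
  stopifnot(inherits(epi, "epi_inputs"))
  m <- epi$mortality
  if (any(m$rate < 0 | m$rate > 1)) abort("Mortality rates outside [0, 1].")
  mono <- m |>
    dplyr::filter(.data$age >= 60) |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(ok = all(diff(.data$rate) >= 0), .groups = "drop")
  if (!all(mono$ok)) abort("Mortality not monotone non-decreasing above age 60.")
  de <- epi$disease_epi
  rates <- c(de$incidence, de$case_fatality, de$remission, de$prevalence)
  if (any(rates < 0 | rates > 1)) abort("Disease rates outside [0, 1].")
  sums <- epi$exposure |>
    dplyr::group_by(.data$risk_factor, .data$sex, .data$age_lo) |>
    dplyr::summarise(s = sum(.data$prevalence), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort("Exposure prevalences do not sum to 1 within a stratum.")
  }
  if (any(epi$rr$rr < 0)) abort("Negative relative risk.")
  refs <- exposure_bands() |> dplyr::filter(.data$reference)
  ref_rr <- dplyr::inner_join(epi$rr, refs,
                              by = c("risk_factor", "category"))
  if (any(abs(ref_rr$rr - 1) > 1e-12)) {
    abort("Reference exposure category must have relative risk 1.")
  }
  invisible(epi)
}

#' @export
print.epi_inputs <- function(x, ...) {
  cat("<epi_inputs> synthetic epidemiological input set (seed ", x$seed, ")\n",
      sep = "")
  cat("  diseases: ", paste(unique(x$disease_epi$disease), collapse = ", "),
      "\n", sep = "")
  cat("  ages 0-", max(x$mortality$age), ", adults modelled: ",
      round(sum(x$population$persons)), "\n", sep = "")
  invisible(x)
}

#' Generate a weekly store-sales series
#'
#' Simulates per-capita grams purchased per category over consecutive
#' baseline, discount and follow-up phases, with optional 52-week
#' seasonality, a secular slope, a fractional step effect during the
#' discount phase, and multiplicative noise. A fixture for exercising the
#' dietary-response stage; the trial's own percent changes come from its
#' stepped-wedge analysis, which is out of scope here.
#'
#' @param baseline Tibble with `category` and `weight_g` (baseline mean
#'   grams/person/day); a `total` row, if present, is dropped.
#' @param effect Fractional step change during the discount phase: a single
#'   number or a vector named by category (unnamed categories get 0).
#' @param n_baseline,n_discount,n_followup Weeks per phase (49/24/24 as in
#'   the trial design).
#' @param seasonal_amplitude Relative amplitude of a 52-week sinusoid.
#' @param slope Relative secular trend per 52 weeks.
#' @param noise_sd Relative SD of multiplicative Gaussian noise.
#' @param seed Integer seed.
#' @return Tibble with `week`, `phase`, `category`, `grams` (all `grams >= 0`).
#' @export
generate_sales_series <- function(baseline, effect = 0,
                                  n_baseline = 49, n_discount = 24,
                                  n_followup = 24,
                                  seasonal_amplitude = 0.05, slope = 0,
                                  noise_sd = 0.05, seed = 1) {
  baseline <- dplyr::filter(baseline, .data$category != "total")
  if (any(baseline$weight_g < 0)) abort("Baseline weights must be non-negative.")
  if (!all(is.finite(effect))) abort("Step effects must be finite.")
  if (is.null(names(effect))) {
    if (length(effect) != 1) {
      abort("Unnamed `effect` must be a single number applied to all categories.")
    }
    eff <- setNames(rep(effect, nrow(baseline)), baseline$category)
  } else {
    unknown <- setdiff(names(effect), baseline$category)
    if (length(unknown) > 0) {
      abort(paste0("`effect` names not in baseline: ",
                   paste(unknown, collapse = ", ")))
    }
    eff <- setNames(rep(0, nrow(baseline)), baseline$category)
    eff[names(effect)] <- effect
  }
  if (any(baseline$weight_g == 0 & eff[baseline$category] != 0)) {
    abort("Nonzero step effect on a zero-baseline category.")
  }
  n_weeks <- n_baseline + n_discount + n_followup
  phases <- rep(c("baseline", "discount", "followup"),
                c(n_baseline, n_discount, n_followup))
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      baseline |> dplyr::select("category", "weight_g"),
      tibble::tibble(week = seq_len(n_weeks), phase = phases)
    )
    grid |>
      dplyr::mutate(
        season = 1 + seasonal_amplitude * sin(2 * pi * .data$week / 52),
        trend = 1 + slope * .data$week / 52,
        step = 1 + eff[.data$category] * (.data$phase == "discount"),
        grams = pmax(0, .data$weight_g * .data$season * .data$trend *
                       .data$step * (1 + rnorm(dplyr::n(), 0, noise_sd)))
      ) |>
      dplyr::select("week", "phase", "category", "grams") |>
      dplyr::arrange(.data$week, .data$category)
  })
}

#' Recover the discount-phase step effect from a sales series
#'
#' Simple mean-ratio estimator: discount-phase mean over baseline-phase mean
#' minus one, per category. Used only for fixture validation; it does not
#' adjust for seasonal phase imbalance or trends.
#'
#' @param sales Tibble from [generate_sales_series()].
#' @return Tibble with `category` and `effect_hat` (fractional).
#' @export
recover_step_effect <- function(sales) {
  sales |>
    dplyr::filter(.data$phase %in% c("baseline", "discount")) |>
    dplyr::group_by(.data$category, .data$phase) |>
    dplyr::summarise(m = mean(.data$grams), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "m") |>
    dplyr::mutate(effect_hat = .data$discount / .data$baseline - 1) |>
    dplyr::select("category", "effect_hat")
}

#' Write or read an epidemiological input set as CSV files
#'
#' Serialises each component to a delimited text file (`mortality.csv`,
#' `disease_epi.csv`, `exposure.csv`, `rr.csv`, `unit_costs.csv`,
#' `population.csv`, `background_morbidity.csv`) with header rows, UTF-8
#' encoding and decimal points, so users can substitute measured inputs in
#' the same schema.
#'
#' @param epi An `epi_inputs` object.
#' @param dir Directory to write to / read from (created if absent).
#' @return `write_epi_inputs()`: the directory, invisibly.
#'   `read_epi_inputs()`: an `epi_inputs` object.
#' @export
write_epi_inputs <- function(epi, dir) {
  stopifnot(inherits(epi, "epi_inputs"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp <- c("mortality", "disease_epi", "exposure", "rr", "unit_costs",
            "population", "background_morbidity")
  for (nm in comp) {
    readr::write_csv(epi[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  readr::write_csv(tibble::tibble(seed = epi$seed), file.path(dir, "seed.csv"))
  invisible(dir)
}

#' @rdname write_epi_inputs
#' @export
read_epi_inputs <- function(dir) {
  comp <- c("mortality", "disease_epi", "exposure", "rr", "unit_costs",
            "population", "background_morbidity")
  out <- lapply(comp, function(nm) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                    show_col_types = FALSE, progress = FALSE)
  })
  names(out) <- comp
  seed_path <- file.path(dir, "seed.csv")
  out$seed <- if (file.exists(seed_path)) {
    readr::read_csv(seed_path, show_col_types = FALSE, progress = FALSE)$seed[1]
  } else {
    NA_integer_
  }
  structure(out, class = "epi_inputs")
}
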