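#' Default pipeline configuration
#'
#' A complete run configuration as a plain named list (YAML-serialisable).
#' Any subset can be overridden; [run_pipeline()] merges overrides into
#' these defaults. Notable keys: `arm` and `period` select the trial
#' contrast; `inputs$synthetic$seed` generates the epidemiological inputs
#' (set `inputs$dir` instead to read measured inputs from CSV);
#' `effects = "none"` forces a null intervention (zero risk-factor shifts);
#' `psa$n_iterations` sets the Monte Carlo size.
#'
#' @return Named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    arm = "discount_only",
    period = "during",
    inputs = list(synthetic = list(seed = 1)),
    effects = "trial",
    diet = list(pct_price_change = -20),
    bmi = list(coef_adult = default_energy_bmi_coef(),
               coef_child = default_energy_bmi_coef(),
               duration_years = 1),
    model = list(decay_rate = 0.5, discount_rate = 0.03),
    background = list(),
    costs = list(cpi_old = 99.8, cpi_new = 104.8,
                 indigenous_factor = 1.19, threshold = 50000,
                 n_stores_per_arm = 10),
    psa = list(n_iterations = 2000, seed = 42)
  )
}

#' Risk-factor shifts implied by the trial's dietary changes
#'
#' Maps the dietary deltas of one arm and period onto the four modelled
#' risk factors: total energy change becomes a population BMI shift (via
#' the energy-flux coefficients), total sodium change maps directly, and
#' the fruit and vegetable shifts are the summed fresh/other (fresh+frozen/
#' other) category changes with CI half-widths combined in quadrature.
#'
#' @param changes Absolute-basis diet changes ([trial_diet_changes()]).
#' @param baseline Baseline diet ([trial_baseline_diet()]).
#' @param arm,period Trial contrast to use.
#' @param coef_adult,coef_child,duration_years Passed to the BMI model.
#' @return Tibble with `risk_factor`, `delta0`, `lo`, `hi` in the risk
#'   factors' continuous units (BMI units, mg sodium, g fruit, g veg).
#' @export
risk_factor_shifts <- function(changes, baseline,
                               arm = "discount_only", period = "during",
                               coef_adult = default_energy_bmi_coef(),
                               coef_child = default_energy_bmi_coef(),
                               duration_years = 1) {
  check_arm(arm)
  check_period(period)
  arm_ <- arm; period_ <- period
  sub <- changes |>
    dplyr::filter(.data$arm == arm_, .data$period == period_)

  bmi <- sub |>
    dplyr::filter(.data$category == "total", .data$metric == "energy") |>
    percent_from_absolute(baseline) |>
    bmi_change_from_energy(coef_adult = coef_adult, coef_child = coef_child,
                           duration_years = duration_years)

  sodium <- sub |>
    dplyr::filter(.data$category == "total", .data$metric == "sodium")

  sum_cats <- function(cats) {
    rows <- sub |>
      dplyr::filter(.data$category %in% cats, .data$metric == "weight")
    hw <- sqrt(sum(((rows$hi - rows$lo) / 2)^2))
    c(mean = sum(rows$mean), lo = sum(rows$mean) - hw, hi = sum(rows$mean) + hw)
  }
  fruit <- sum_cats(c("fruit_fresh", "fruit_other"))
  veg <- sum_cats(c("vegetables_fresh_frozen", "vegetables_other"))

  tibble::tibble(
    risk_factor = c("bmi", "sodium", "fruit", "vegetable"),
    delta0 = c(bmi$delta_bmi, sodium$mean, fruit[["mean"]], veg[["mean"]]),
    lo = c(bmi$delta_bmi_lo, sodium$lo, fruit[["lo"]], veg[["lo"]]),
    hi = c(bmi$delta_bmi_hi, sodium$hi, fruit[["hi"]], veg[["hi"]])
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full cost-effectiveness pipeline
#'
#' Orchestrates every stage for one arm and period: input loading or
#' synthesis, dietary deltas and price elasticities, BMI/sodium/fruit/
#' vegetable risk-factor shifts, the proportional multi-state lifetable,
#' intervention costing with CPI deflation and treatment cost deltas, the
#' ICER, and Monte Carlo uncertainty. Writes `elasticities.csv`,
#' `diet_deltas.csv`, `daly_results.csv`, `case_years.csv`,
#' `cost_summary.csv`, `icer.csv`, `psa_draws.csv`, `ce_plane.csv` and
#' `run_log.txt` to `out_dir`. Runs with identical configuration and seed
#' produce byte-identical outputs.
#'
#' @param config Configuration list (merged over [default_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param seed Optional master seed overriding `inputs$synthetic$seed`
#'   (and, incremented by one, `psa$seed`).
#' @return Invisibly, a list with `elasticities`, `shifts`, `daly`
#'   (`pmslt_result`), `costs`, `icer`, `psa` (`psa_result` or NULL) and
#'   the resolved `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  check_arm(cfg$arm)
  check_period(cfg$period)
  if (!is.null(seed)) {
    cfg$inputs$synthetic$seed <- seed
    cfg$psa$seed <- seed + 1
  }

  # --- inputs ------------------------------------------------------------
  epi <- if (!is.null(cfg$inputs$dir)) {
    read_epi_inputs(cfg$inputs$dir)
  } else {
    generate_epi_inputs(seed = cfg$inputs$synthetic$seed)
  }
  validate_epi_inputs(epi)
  baseline <- trial_baseline_diet()
  changes <- trial_diet_changes()

  # --- diet response -----------------------------------------------------
  elasticities <- elasticity_table(changes, baseline, arm = cfg$arm,
                                   pct_price_change = cfg$diet$pct_price_change)
  deltas <- changes |>
    dplyr::filter(.data$arm == cfg$arm, .data$period == cfg$period)

  # --- risk-factor shifts ------------------------------------------------
  shifts <- risk_factor_shifts(
    changes, baseline, arm = cfg$arm, period = cfg$period,
    coef_adult = cfg$bmi$coef_adult, coef_child = cfg$bmi$coef_child,
    duration_years = cfg$bmi$duration_years
  )
  if (identical(cfg$effects, "none")) {
    shifts$delta0 <- shifts$lo <- shifts$hi <- 0
  }
  background <- if (length(cfg$background) > 0) {
    tibble::tibble(risk_factor = names(cfg$background),
                   delta0 = unlist(cfg$background))
  } else {
    NULL
  }

  # --- lifetable ---------------------------------------------------------
  engine <- pmslt_engine(
    epi, background = background,
    decay_rate = cfg$model$decay_rate,
    discount_rate = cfg$model$discount_rate,
    max_age = cfg$model$max_age
  )
  daly <- engine$eval(dplyr::select(shifts, "risk_factor", "delta0"))

  # --- costs and ICER ----------------------------------------------------
  arm_costs <- arm_cost_summary(n_stores_per_arm = cfg$costs$n_stores_per_arm)
  this_arm <- dplyr::filter(arm_costs, .data$arm == cfg$arm)
  intervention_nominal <- this_arm$total_aud
  intervention_2011 <- cpi_deflate(intervention_nominal,
                                   cfg$costs$cpi_old, cfg$costs$cpi_new)
  treat_delta <- treatment_cost_delta(
    daly$case_year_deltas, epi$unit_costs,
    indigenous_factor = cfg$costs$indigenous_factor,
    discount_rate = cfg$model$discount_rate
  )
  net_cost <- intervention_2011 + treat_delta
  icer <- compute_icer(net_cost, daly$dalys_averted,
                       threshold = cfg$costs$threshold)
  costs <- tibble::tibble(
    arm = cfg$arm, period = cfg$period,
    intervention_nominal_aud = intervention_nominal,
    intervention_aud2011 = intervention_2011,
    treatment_cost_delta_aud2011 = treat_delta,
    net_cost_aud2011 = net_cost
  )

  # --- uncertainty -------------------------------------------------------
  psa <- NULL
  if (cfg$psa$n_iterations > 0) {
    se <- (shifts$hi - shifts$lo) / 2 / 1.96
    params <- tibble::tibble(
      parameter = shifts$risk_factor,
      dist = ifelse(se == 0, "fixed", "normal"),
      mean = shifts$delta0, sd = se
    )
    model_fn <- function(draw) {
      res <- engine$eval(tibble::tibble(
        risk_factor = names(draw), delta0 = unlist(draw)
      ))
      td <- treatment_cost_delta(
        res$case_year_deltas, epi$unit_costs,
        indigenous_factor = cfg$costs$indigenous_factor,
        discount_rate = cfg$model$discount_rate
      )
      list(dalys_averted = res$dalys_averted,
           net_cost = intervention_2011 + td)
    }
    psa <- run_psa(model_fn, psa_spec(params,
                                      n_iterations = cfg$psa$n_iterations,
                                      seed = cfg$psa$seed))
  }

  result <- list(elasticities = elasticities, diet_deltas = deltas,
                 shifts = shifts, daly = daly, costs = costs, icer = icer,
                 psa = psa, epi = epi, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, file) readr::write_csv(df, file.path(out_dir, file))
  cfg <- result$config

  w(result$elasticities |>
      dplyr::rename(pct_quantity_change_at_20pct_fall = "pct_quantity_change",
                    elasticity_per_1pct_fall = "elasticity"),
    "elasticities.csv")
  w(result$diet_deltas, "diet_deltas.csv")

  daly_sum <- tibble::tibble(
    arm = cfg$arm, period = cfg$period,
    dalys_mean = result$daly$dalys_averted,
    dalys_lo = NA_real_, dalys_hi = NA_real_
  )
  if (!is.null(result$psa)) {
    s <- dplyr::filter(result$psa$summary, .data$output == "dalys_averted")
    daly_sum$dalys_lo <- s$lo
    daly_sum$dalys_hi <- s$hi
  }
  w(daly_sum, "daly_results.csv")
  w(result$daly$case_year_deltas, "case_years.csv")
  w(result$costs, "cost_summary.csv")
  w(dplyr::mutate(result$icer, arm = cfg$arm, period = cfg$period,
                  .before = 1), "icer.csv")
  if (!is.null(result$psa)) {
    w(result$psa$draws, "psa_draws.csv")
    w(dplyr::select(result$psa$draws, "dalys_averted", "net_cost"),
      "ce_plane.csv")
  }

  log_lines <- c(
    paste0("pricehealth version: ",
           as.character(utils::packageVersion("pricehealth"))),
    paste0("arm: ", cfg$arm, "  period: ", cfg$period),
    paste0("synthetic input seed: ",
           cfg$inputs$synthetic$seed %||% "(inputs read from dir)"),
    paste0("psa seed: ", cfg$psa$seed,
           "  iterations: ", cfg$psa$n_iterations),
    paste0("input hash: ", rlang::hash(result$epi)),
    paste0("config hash: ", rlang::hash(cfg)),
    paste0("outputs: ", paste(sort(list.files(out_dir, pattern = "\\.csv$")),
                              collapse = ", "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
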