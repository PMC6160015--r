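#' Convert baseline diet to long form
#'
#' Internal helper mapping the wide baseline table (`weight_g`, `energy_mj`,
#' `sodium_mg`) to one `(category, metric, baseline)` row per metric.
#' @noRd
baseline_long <- function(baseline) {
  baseline |>
    tidyr::pivot_longer(
      cols = c("weight_g", "energy_mj", "sodium_mg"),
      names_to = "metric", values_to = "baseline"
    ) |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      weight_g = "weight", energy_mj = "energy", sodium_mg = "sodium"
    ))
}

check_unique_categories <- function(baseline) {
  if (anyDuplicated(baseline$category) > 0) {
    abort("Baseline diet categories must be unique.")
  }
  if (any(baseline$weight_g < 0 | baseline$energy_mj < 0 | baseline$sodium_mg < 0)) {
    abort("Baseline diet values must be non-negative.")
  }
  invisible(baseline)
}

#' Convert percent dietary changes to absolute per-capita changes
#'
#' The trial analysis reports percent changes in store sales relative to the
#' 49-week pre-trial baseline; absolute daily per-capita changes are obtained
#' by multiplying the mean baseline value of each category and metric by the
#' percent change (mean and both 95% CI bounds scale identically).
#'
#' @param changes Tibble with columns `category`, `metric`, `mean`, `lo`,
#'   `hi` where the value columns are percent (e.g. `11.07` for +11.07%);
#'   extra columns (`arm`, `period`) pass through.
#' @param baseline Baseline diet tibble as from [trial_baseline_diet()].
#' @return The input tibble with `mean`, `lo`, `hi` in absolute metric units
#'   (g, MJ or mg per person per day) and `basis = "absolute"`.
#' @seealso [percent_from_absolute()] for the inverse.
#' @export
#' @examples
#' baseline <- trial_baseline_diet()
#' pct <- tibble::tibble(category = "cereals", metric = "weight",
#'                       mean = 11.07, lo = 1.8, hi = 21.1)
#' absolute_from_percent(pct, baseline)
absolute_from_percent <- function(changes, baseline) {
  check_unique_categories(baseline)
  out <- changes |>
    dplyr::inner_join(baseline_long(baseline), by = c("category", "metric"))
  if (nrow(out) < nrow(changes)) {
    missing <- setdiff(changes$category, baseline$category)
    abort(paste0("Categories absent from baseline: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- out$baseline == 0 & (out$mean != 0 | out$lo != 0 | out$hi != 0)
  if (any(bad)) {
    abort(paste0(
      "Zero baseline with nonzero percent change (scale undefined) for: ",
      paste(unique(out$category[bad]), collapse = ", ")
    ))
  }
  out |>
    dplyr::mutate(
      mean = .data$mean / 100 * .data$baseline,
      lo = .data$lo / 100 * .data$baseline,
      hi = .data$hi / 100 * .data$baseline,
      basis = "absolute"
    ) |>
    dplyr::select(-"baseline")
}

#' Convert absolute dietary changes to percent of baseline
#'
#' Inverse of [absolute_from_percent()]: divides the absolute change (and its
#' CI bounds) by the category baseline. Used to express quantity responses to
#' the 20% price fall as percent of baseline demand.
#'
#' @inheritParams absolute_from_percent
#' @param changes Tibble with `category`, `metric`, `mean`, `lo`, `hi` in
#'   absolute metric units.
#' @return The input tibble with value columns in percent and
#'   `basis = "percent"`.
#' @export
#' @examples
#' baseline <- trial_baseline_diet()
#' abs_chg <- tibble::tibble(category = "fruit_fresh", metric = "weight",
#'                           mean = 6.9, lo = 1.9, hi = 12.5)
#' percent_from_absolute(abs_chg, baseline)  # 19.06% mean
percent_from_absolute <- function(changes, baseline) {
  check_unique_categories(baseline)
  out <- changes |>
    dplyr::inner_join(baseline_long(baseline), by = c("category", "metric"))
  if (nrow(out) < nrow(changes)) {
    missing <- setdiff(changes$category, baseline$category)
    abort(paste0("Categories absent from baseline: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(out$baseline == 0)) {
    abort(paste0(
      "Zero baseline (percent change undefined) for: ",
      paste(unique(out$category[out$baseline == 0]), collapse = ", ")
    ))
  }
  out |>
    dplyr::mutate(
      mean = .data$mean / .data$baseline * 100,
      lo = .data$lo / .data$baseline * 100,
      hi = .data$hi / .data$baseline * 100,
      basis = "percent"
    ) |>
    dplyr::select(-"baseline")
}

#' Own- and cross-price elasticities from percent quantity changes
#'
#' Arc-style elasticity: the percent change in quantity demanded per 1% price
#' fall, computed as the percent quantity change over the discount period
#' divided by the magnitude of the percent price change (20% here). The sign
#' convention is positive when quantity rises as price falls. CI bounds are
#' transformed identically.
#'
#' @param pct_changes Tibble of percent quantity changes (`category`, `mean`,
#'   `lo`, `hi` in percent of baseline).
#' @param pct_price_change Percent price change; default -20 (a 20% fall).
#' @return Tibble with `category`, `pct_quantity_change` (and CI), and
#'   `elasticity`, `elasticity_lo`, `elasticity_hi` per 1% price fall.
#' @export
#' @examples
#' pc <- tibble::tibble(category = "cereals", mean = 11.07,
#'                      lo = 1.8, hi = 21.1)
#' price_elasticity(pc)  # elasticity 0.55 per 1% price fall
price_elasticity <- function(pct_changes, pct_price_change = -20) {
  if (length(pct_price_change) != 1 || pct_price_change == 0) {
    abort("`pct_price_change` must be a single nonzero percent.")
  }
  p <- abs(pct_price_change)
  pct_changes |>
    dplyr::mutate(
      pct_quantity_change = .data$mean,
      elasticity = .data$mean / p,
      elasticity_lo = .data$lo / p,
      elasticity_hi = .data$hi / p
    )
}

#' Sum grouped food categories before percent conversion
#'
#' Builds grouped rows (e.g. all fruit plus vegetables, discounted drinks) by
#' summing the constituent categories' baselines and absolute changes; CI
#' half-widths are combined in quadrature assuming independence. Percent
#' changes for groups must be computed from these summed absolutes, never by
#' averaging constituent percents.
#'
#' @param changes Absolute-basis changes tibble for one arm, period, metric.
#' @param baseline Baseline diet tibble.
#' @param groups Named list of character vectors of constituent categories.
#' @return List with `changes` (one absolute row per group) and `baseline`
#'   (one row per group).
#' @export
aggregate_categories <- function(changes, baseline, groups) {
  check_unique_categories(baseline)
  grp_change <- purrr::imap_dfr(groups, function(cats, name) {
    rows <- dplyr::filter(changes, .data$category %in% cats)
    if (nrow(rows) != length(cats)) {
      abort(paste0("Group '", name, "' references categories absent from changes."))
    }
    tibble::tibble(
      category = name,
      metric = rows$metric[1],
      basis = "absolute",
      mean = sum(rows$mean),
      lo = sum(rows$mean) - sqrt(sum(((rows$hi - rows$lo) / 2)^2)),
      hi = sum(rows$mean) + sqrt(sum(((rows$hi - rows$lo) / 2)^2))
    )
  })
  grp_base <- purrr::imap_dfr(groups, function(cats, name) {
    rows <- dplyr::filter(baseline, .data$category %in% cats)
    tibble::tibble(
      category = name,
      weight_g = sum(rows$weight_g),
      energy_mj = sum(rows$energy_mj),
      sodium_mg = sum(rows$sodium_mg)
    )
  })
  list(changes = grp_change, baseline = grp_base)
}

#' Aggregate category changes to per-metric totals
#'
#' Sums the category mean changes within each metric for a single arm and
#' period. The total's CI is not the sum of category CIs: when the trial
#' supplies its own total row that should be preferred; in its absence the
#' half-widths are combined in quadrature (independence assumption).
#' Rows with `category == "total"` are dropped before summing.
#'
#' @param changes Absolute-basis changes tibble for one arm and period.
#' @return Tibble with one row per metric: `metric`, `mean`, `lo`, `hi`,
#'   `n_categories`.
#' @export
aggregate_totals <- function(changes) {
  if (nrow(changes) == 0) {
    return(tibble::tibble(metric = character(), mean = numeric(),
                          lo = numeric(), hi = numeric(),
                          n_categories = integer()))
  }
  for (key in intersect(c("arm", "period"), names(changes))) {
    if (dplyr::n_distinct(changes[[key]]) > 1) {
      abort(paste0("`changes` mixes multiple values of `", key,
                   "`; aggregate one arm/period at a time."))
    }
  }
  changes |>
    dplyr::filter(.data$category != "total") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      n_categories = dplyr::n(),
      hw = sqrt(sum(((.data$hi - .data$lo) / 2)^2)),
      mean = sum(.data$mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(lo = .data$mean - .data$hw, hi = .data$mean + .data$hw) |>
    dplyr::select("metric", "mean", "lo", "hi", "n_categories")
}

#' Elasticity table for one arm's discount-period response
#'
#' Convenience wrapper reproducing the published elasticity table: takes
#' absolute during-period weight changes, expresses them as percent of
#' baseline, and converts to per-1% elasticities with rounded display
#' columns (percent to whole numbers, elasticities to 2 d.p., half away
#' from zero).
#'
#' @param changes Diet changes tibble (as [trial_diet_changes()]).
#' @param baseline Baseline diet tibble.
#' @param arm Strategy arm; the published table corresponds to
#'   `"discount_only"`.
#' @param pct_price_change Percent price change, default -20.
#' @return Tibble with categories, percent quantity responses and
#'   elasticities, plus `pct_display` and `elasticity_display`.
#' @export
elasticity_table <- function(changes, baseline, arm = "discount_only",
                             pct_price_change = -20) {
  check_arm(arm)
  arm_ <- arm
  changes |>
    dplyr::filter(.data$arm == arm_, .data$period == "during",
                  .data$metric == "weight") |>
    percent_from_absolute(baseline) |>
    price_elasticity(pct_price_change) |>
    dplyr::mutate(
      pct_display = round_half_up(.data$pct_quantity_change, 0),
      elasticity_display = round_half_up(.data$elasticity, 2)
    ) |>
    dplyr::select("category", "pct_quantity_change", "pct_display",
                  "elasticity", "elasticity_lo", "elasticity_hi",
                  "elasticity_display")
}
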