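#' Packaged trial inputs
#'
#' The package ships the published inputs of the 20% price-discount trial
#' run in 20 remote Indigenous Australian community stores: the baseline
#' per-capita daily diet for the 22 printed food and beverage categories,
#' the absolute dietary changes (with 95% CIs) by strategy arm and trial
#' period, the itemised intervention cost inventory, and the per-arm split
#' of the discount implementation cost. All amounts are nominal AUD 2012-14;
#' diet is grams, megajoules and milligrams per person per day.
#'
#' @return A tibble. `trial_baseline_diet()`: one row per category (plus a
#'   `total` row) with `weight_g`, `energy_mj`, `sodium_mg`.
#'   `trial_diet_changes()`: columns `arm`, `period`, `category`, `metric`
#'   (`weight`/`energy`/`sodium`), `basis` (`absolute`), `mean`, `lo`, `hi`.
#'   `trial_cost_items()`: `item`, `strategy` (`discount`/`education`),
#'   `phase` (`design`/`implementation`), `amount_aud`, `hours`.
#'   `trial_arm_discount_implementation()`: `arm`, `amount_aud`.
#' @name trial_data
NULL

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pricehealth")
  if (path == "") {
    # during in-source development (pkgload) inst/ is on the search path root
    path <- system.file("inst", "extdata", file, package = "pricehealth")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
}

#' @rdname trial_data
#' @export
trial_baseline_diet <- function() {
  read_extdata("baseline_diet.csv")
}

#' @rdname trial_data
#' @export
trial_diet_changes <- function() {
  read_extdata("diet_changes.csv")
}

#' @rdname trial_data
#' @export
trial_cost_items <- function() {
  read_extdata("cost_items.csv")
}

#' @rdname trial_data
#' @export
trial_arm_discount_implementation <- function() {
  read_extdata("arm_discount_implementation.csv")
}

#' Trial population structure
#'
#' The 20 trial communities comprised 8,515 residents, 41% children and
#' 59% adults; the health model applies to the adult population only.
#'
#' @return A one-row tibble with `total_persons`, `frac_children`,
#'   `frac_adults`, `n_adults` and `n_stores`.
#' @export
trial_population <- function() {
  tibble::tibble(
    total_persons = 8515,
    frac_children = 0.41,
    frac_adults = 0.59,
    n_adults = round(8515 * 0.59),
    n_stores = 20
  )
}

#' Risk-factor categories modelled in the health pathway
#'
#' @return Character vector of the four dietary risk factors.
#' @export
risk_factors <- function() c("bmi", "sodium", "fruit", "vegetable")

#' Diseases modelled in the lifetable
#'
#' @return Character vector of the five modelled diseases.
#' @export
modelled_diseases <- function() {
  c("ihd", "stroke", "hypertensive_heart_disease", "diabetes", "colon_cancer")
}
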