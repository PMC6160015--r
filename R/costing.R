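#' Sum an itemised cost ledger
#'
#' Exact integer-dollar sums of cost items by any grouping (strategy, phase,
#' ...). Hours sum alongside dollars when present.
#'
#' @param items Cost-item tibble with `amount_aud` and optionally `hours`
#'   (as from [trial_cost_items()]).
#' @param by Character vector of grouping columns; `NULL` sums everything.
#' @return Tibble with the grouping columns, `total_aud`, `total_hours`
#'   (NA-tolerant) and `n_items`.
#' @export
#' @examples
#' sum_ledger(trial_cost_items(), by = "strategy")
sum_ledger <- function(items, by = NULL) {
  ok_strategy <- c("discount", "education")
  ok_phase <- c("design", "implementation")
  if ("strategy" %in% names(items) && !all(items$strategy %in% ok_strategy)) {
    abort(paste0("Unknown strategy label: ",
                 paste(setdiff(items$strategy, ok_strategy), collapse = ", ")))
  }
  if ("phase" %in% names(items) && !all(items$phase %in% ok_phase)) {
    abort(paste0("Unknown phase label: ",
                 paste(setdiff(items$phase, ok_phase), collapse = ", ")))
  }
  has_hours <- "hours" %in% names(items)
  items |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by %||% character(0)))) |>
    dplyr::summarise(
      total_aud = sum(.data$amount_aud),
      total_hours = if (has_hours) sum(.data$hours, na.rm = TRUE) else NA_real_,
      n_items = dplyr::n(),
      .groups = "drop"
    )
}

#' Average cost per store
#'
#' @param total_aud Total nominal cost.
#' @param n_stores Number of stores it covers.
#' @return Whole dollars, rounded half away from zero.
#' @export
per_store_average <- function(total_aud, n_stores) {
  stopifnot(n_stores > 0)
  round_half_up(total_aud / n_stores, 0)
}

#' Per-arm cost summary by strategy and phase
#'
#' Reconstructs the trial's cost summary: design-phase discount costs were
#' shared equally between the two arms (half the pooled design total,
#' rounded half away from zero to whole dollars); implementation discount
#' costs (dominated by the reimbursement of actual sales) are arm-specific
#' inputs; the consumer-education strategy was delivered only in the
#' combined arm.
#'
#' @param items Cost-item tibble ([trial_cost_items()]).
#' @param arm_impl Per-arm discount implementation costs
#'   ([trial_arm_discount_implementation()]).
#' @param n_stores_per_arm Stores per arm; default 10.
#' @return Tibble with one row per arm: design, implementation and total
#'   dollars by strategy, the arm total and the per-store average.
#' @export
arm_cost_summary <- function(items = trial_cost_items(),
                             arm_impl = trial_arm_discount_implementation(),
                             n_stores_per_arm = 10) {
  check_arm(arm_impl$arm)
  pooled <- sum_ledger(items, by = c("strategy", "phase"))
  design_discount_per_arm <- round_half_up(
    pooled$total_aud[pooled$strategy == "discount" & pooled$phase == "design"] / 2, 0
  )
  edu_design <- pooled$total_aud[pooled$strategy == "education" & pooled$phase == "design"]
  edu_impl <- pooled$total_aud[pooled$strategy == "education" & pooled$phase == "implementation"]
  arm_impl |>
    dplyr::mutate(
      discount_design = design_discount_per_arm,
      discount_implementation = .data$amount_aud,
      education_design = ifelse(.data$arm == "discount_plus_education", edu_design, 0),
      education_implementation = ifelse(.data$arm == "discount_plus_education", edu_impl, 0),
      discount_total = .data$discount_design + .data$discount_implementation,
      education_total = .data$education_design + .data$education_implementation,
      total_aud = .data$discount_total + .data$education_total,
      per_store_aud = per_store_average(.data$total_aud, n_stores_per_arm)
    ) |>
    dplyr::select(-"amount_aud")
}

#' CPI deflation factor and deflated amounts
#'
#' Nominal costs spent over 2012-14 are expressed in 2011 dollars with a
#' single consumer-price-index step: the deflation factor is
#' `(cpi_new - cpi_old) / cpi_new` (4.77% for the trial's indices, printed
#' as 4.7%), and `cpi_deflate()` multiplies by `cpi_old / cpi_new`, i.e.
#' `1 - factor`. Full precision is carried internally; only display output
#' is rounded.
#'
#' @param amount Nominal amount(s).
#' @param cpi_old,cpi_new CPI index values for the target (2011) and source
#'   (2013) price years; defaults 99.8 and 104.8.
#' @return `cpi_deflate()`: deflated amount(s); `cpi_deflation_factor()`:
#'   the proportional deflation.
#' @export
#' @examples
#' cpi_deflation_factor()           # 0.0477...
#' cpi_deflate(214918)              # about 204,664 AUD2011
cpi_deflate <- function(amount, cpi_old = 99.8, cpi_new = 104.8) {
  if (cpi_new <= 0 || cpi_old <= 0) abort("CPI indices must be positive.")
  amount * cpi_old / cpi_new
}

#' @rdname cpi_deflate
#' @export
cpi_deflation_factor <- function(cpi_old = 99.8, cpi_new = 104.8) {
  if (cpi_new <= 0) abort("CPI indices must be positive.")
  (cpi_new - cpi_old) / cpi_new
}

#' Change in treatment costs from disease case-year deltas
#'
#' Values each disease's change in prevalent case-years (or incident cases,
#' for diseases costed per incident case) at its unit treatment cost,
#' applies the loading for the additional cost of treating Indigenous
#' Australians (x1.19), and discounts each year of accrual to present
#' value. Positive = added treatment cost (more disease than the
#' comparator); negative = a cost-offset.
#'
#' @param case_year_deltas Tibble from [run_lifetable()] (`tidy()` of a
#'   `pmslt_result`): `disease`, `year`, `delta_case_years`,
#'   `delta_incident_cases`, `cost_basis`.
#' @param unit_costs Tibble with `disease`, `unit_cost_aud2011`,
#'   `cost_basis`.
#' @param indigenous_factor Multiplicative loading; default 1.19.
#' @param discount_rate Annual discount rate; default 0.03.
#' @return Net change in treatment costs, AUD2011 (scalar).
#' @export
treatment_cost_delta <- function(case_year_deltas, unit_costs,
                                 indigenous_factor = 1.19,
                                 discount_rate = 0.03) {
  nz <- case_year_deltas |>
    dplyr::filter(.data$delta_case_years != 0 | .data$delta_incident_cases != 0)
  missing <- setdiff(unique(nz$disease), unit_costs$disease)
  if (length(missing) > 0) {
    abort(paste0("No unit cost supplied for disease(s) with nonzero deltas: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(nz) == 0) return(0)
  nz |>
    dplyr::left_join(
      dplyr::select(unit_costs, "disease", "unit_cost_aud2011",
                    uc_basis = "cost_basis"),
      by = "disease"
    ) |>
    dplyr::mutate(
      quantity = ifelse(.data$uc_basis == "per_incident_case",
                        .data$delta_incident_cases, .data$delta_case_years),
      cost = discount_value(
        .data$quantity * .data$unit_cost_aud2011 * indigenous_factor,
        .data$year, discount_rate
      )
    ) |>
    dplyr::pull("cost") |>
    sum()
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Net cost (intervention cost plus added treatment cost, less offsets)
#' per DALY averted, compared against the conventional Australian
#' willingness-to-pay threshold of $50,000 per DALY. An intervention that
#' costs more and worsens health is *dominated* (no ratio is reported); one
#' that saves money and improves health is *dominant*.
#'
#' @param net_cost Net cost(s), AUD2011.
#' @param dalys_averted DALYs averted (negative = net health loss).
#' @param threshold Willingness-to-pay per DALY averted; default 50,000.
#' @return Tibble with `net_cost`, `dalys_averted`, `icer` (NA when no
#'   ratio applies), `classification` (`dominated`, `dominant`, `ratio`,
#'   `no_effect`) and `below_threshold` (NA unless a ratio over positive
#'   DALYs).
#' @export
#' @examples
#' compute_icer(5e5, -21)   # dominated
#' compute_icer(40000, 1)   # $40,000/DALY, below threshold
compute_icer <- function(net_cost, dalys_averted, threshold = 50000) {
  tibble::tibble(net_cost = net_cost, dalys_averted = dalys_averted) |>
    dplyr::mutate(
      classification = dplyr::case_when(
        .data$dalys_averted == 0 ~ "no_effect",
        .data$net_cost > 0 & .data$dalys_averted < 0 ~ "dominated",
        .data$net_cost < 0 & .data$dalys_averted > 0 ~ "dominant",
        TRUE ~ "ratio"
      ),
      icer = ifelse(.data$classification == "ratio",
                    .data$net_cost / .data$dalys_averted, NA_real_),
      below_threshold = ifelse(
        .data$classification == "ratio" & .data$dalys_averted > 0,
        .data$icer <= threshold, NA
      ),
      threshold = threshold
    )
}
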