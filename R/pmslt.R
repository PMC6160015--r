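#' Exponential decay of a behavioural effect
#'
#' Dietary behaviour change is hard to maintain: effects are assumed to
#' decay exponentially at 50% per annum, so little effect persists beyond
#' five years (`0.5^5 = 0.03125` of the initial effect).
#'
#' @param delta0 Initial effect size (any continuous exposure unit).
#' @param t Years since the intervention (vectorised, `t >= 0`).
#' @param rate Annual decay rate in `[0, 1]`; default 0.5.
#' @return `delta0 * (1 - rate)^t`.
#' @export
#' @examples
#' decay_effect(1, 0:5)
decay_effect <- function(delta0, t, rate = 0.5) {
  if (rate < 0 || rate > 1) abort("`rate` must be in [0, 1].")
  if (any(t < 0)) abort("`t` must be non-negative.")
  delta0 * (1 - rate)^t
}

# transfer matrix for a uniform additive shift of a piecewise-uniform
# banded distribution; mass pushed past either end cap is clamped into the
# extreme band. Rows: source band, columns: destination band; rows sum to 1.
shift_transfer_matrix <- function(lower, upper, delta) {
  k <- length(lower)
  lo_cap <- lower[1]
  hi_cap <- upper[k]
  m <- matrix(0, k, k)
  for (j in seq_len(k)) {
    a <- lower[j] + delta
    b <- upper[j] + delta
    w <- b - a
    for (dest in seq_len(k)) {
      m[j, dest] <- max(0, min(b, upper[dest]) - max(a, lower[dest])) / w
    }
    m[j, 1] <- m[j, 1] + max(0, min(b, lo_cap) - a) / w
    m[j, k] <- m[j, k] + max(0, b - max(a, hi_cap)) / w
  }
  m
}

#' Shift a banded exposure distribution by a uniform amount
#'
#' The underlying continuous exposure is assumed piecewise-uniform within
#' each band; an additive shift `delta` translates the distribution, which
#' is then re-binned onto the original bands. Mass pushed beyond the end
#' caps is clamped into the extreme bands (with a warning when an entire
#' band's mass leaves the support). Prevalences still sum to 1 in every
#' stratum.
#'
#' @param ex Exposure tibble with columns `category`, `lower`, `upper`,
#'   `prevalence` plus any stratum columns (`sex`, `age_lo`, ...). All
#'   strata must share the same band boundaries.
#' @param delta Additive shift in the exposure's continuous units.
#' @return `ex` with updated `prevalence`.
#' @export
#' @examples
#' ex <- tibble::tibble(category = c("low", "high"),
#'                      lower = c(0, 10), upper = c(10, 20),
#'                      prevalence = c(0.5, 0.5))
#' shift_distribution(ex, 10)  # all mass in the upper band
shift_distribution <- function(ex, delta) {
  bands <- dplyr::distinct(ex, .data$category, .data$lower, .data$upper)
  if (anyDuplicated(bands$category) > 0) {
    abort("Band boundaries must be identical across strata.")
  }
  bands <- dplyr::arrange(bands, .data$lower)
  if (delta == 0) return(ex)
  m <- shift_transfer_matrix(bands$lower, bands$upper, delta)
  if (all(bands$lower + delta >= bands$upper[nrow(bands)]) ||
      all(bands$upper + delta <= bands$lower[1])) {
    warn("Shift pushes all exposure mass outside the defined bands; clamped to the extreme band.")
  }
  strata_cols <- setdiff(names(ex), c("category", "lower", "upper", "prevalence"))
  ex |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_cols))) |>
    dplyr::group_modify(function(g, key) {
      g <- g[match(bands$category, g$category), ]
      g$prevalence <- as.vector(g$prevalence %*% m)
      g
    }) |>
    dplyr::ungroup()
}

#' Potential impact fraction of an exposure shift
#'
#' The proportional change in disease incidence caused by moving the
#' exposure distribution from `before` to `after`, given category-specific
#' relative risks: `PIF = (sum(p * RR) - sum(p' * RR)) / sum(p * RR)`.
#' Positive values reduce incidence; negative values (a worsening exposure)
#' increase it. New incidence is `old * (1 - PIF)`. PIFs for several risk
#' factors acting on one disease combine multiplicatively:
#' `1 - PIF_total = prod(1 - PIF_k)` (see [combine_pifs()]).
#'
#' @param before,after Exposure tibbles sharing strata and categories
#'   (columns `category`, `prevalence` plus stratum columns).
#' @param rr Relative-risk tibble with `category`, `rr` and optionally
#'   `disease` (PIFs are then returned per disease).
#' @return Tibble of strata (and disease, if given) with column `pif`.
#' @export
#' @examples
#' before <- tibble::tibble(category = c("a", "b"), prevalence = c(0.5, 0.5))
#' after <- tibble::tibble(category = c("a", "b"), prevalence = c(0, 1))
#' rr <- tibble::tibble(category = c("a", "b"), rr = c(1, 2))
#' potential_impact_fraction(before, after, rr)  # -1/3
potential_impact_fraction <- function(before, after, rr) {
  strata_cols <- setdiff(names(before),
                         c("category", "lower", "upper", "prevalence"))
  join_cols <- c(strata_cols, "category")
  merged <- dplyr::inner_join(
    before |> dplyr::select(dplyr::all_of(join_cols), p = "prevalence"),
    after |> dplyr::select(dplyr::all_of(join_cols), p_new = "prevalence"),
    by = join_cols
  )
  if (nrow(merged) != nrow(before)) {
    abort("`before` and `after` must share identical strata and categories.")
  }
  by_disease <- "disease" %in% names(rr)
  merged <- dplyr::inner_join(merged, rr, by = "category",
                              relationship = "many-to-many")
  out <- merged |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(strata_cols, if (by_disease) "disease")
    ))) |>
    dplyr::summarise(
      denom = sum(.data$p * .data$rr),
      num = sum(.data$p * .data$rr) - sum(.data$p_new * .data$rr),
      .groups = "drop"
    )
  if (any(out$denom == 0)) {
    abort("Potential impact fraction undefined: sum(p * RR) is zero.")
  }
  out |>
    dplyr::mutate(pif = .data$num / .data$denom) |>
    dplyr::select(-"denom", -"num")
}

#' Combine per-risk-factor PIFs multiplicatively
#'
#' @param pifs Tibble with a `pif` column and grouping columns (typically
#'   stratum and `disease`); one row per risk factor within each group.
#' @return Tibble with one combined `pif` per group:
#'   `1 - prod(1 - pif_k)`.
#' @export
combine_pifs <- function(pifs) {
  group_cols <- setdiff(names(pifs), c("pif", "risk_factor"))
  pifs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(pif = 1 - prod(1 - .data$pif), .groups = "drop")
}

#' Annual-cycle three-state disease process for one cohort
#'
#' Difference-equation process on proportions of an initial cohort:
#' well -> case at `incidence * (1 - PIF(t))`, case -> dead-from-disease at
#' the case fatality rate, case -> well at the remission rate. State
#' occupancies always sum to 1; disease prevalence among the living is
#' `case / (well + case)` and the disease's contribution to all-cause
#' mortality is `case_fatality * prevalence`.
#'
#' @param incidence,case_fatality,remission Per-person-year rates: scalars
#'   or vectors of length `horizon` (one per annual cycle).
#' @param p0 Initial prevalence proportion (cases among the living at t=0).
#' @param pif PIF applied to incidence: scalar or length-`horizon` vector.
#' @param horizon Number of annual cycles (>= 1).
#' @return Tibble with one row per cycle boundary (year 0..horizon):
#'   `year`, `well`, `case`, `dead_disease`, `prevalence`,
#'   `mortality_rate`.
#' @export
#' @examples
#' run_disease_model(incidence = 0.1, case_fatality = 0, remission = 0,
#'                   p0 = 0, pif = 0, horizon = 2)  # case = 0.19 at year 2
run_disease_model <- function(incidence, case_fatality, remission = 0,
                              p0 = 0, pif = 0, horizon) {
  stopifnot(horizon >= 1, p0 >= 0, p0 <= 1)
  rep_h <- function(x) if (length(x) == 1) rep(x, horizon) else x
  i <- rep_h(incidence); f <- rep_h(case_fatality)
  r <- rep_h(remission); pf <- rep_h(pif)
  if (any(lengths(list(i, f, r, pf)) != horizon)) {
    abort("Rate vectors must be scalars or length `horizon`.")
  }
  s <- 1 - p0; c_ <- p0; d <- 0
  out <- matrix(NA_real_, horizon + 1, 4,
                dimnames = list(NULL, c("year", "well", "case", "dead_disease")))
  out[1, ] <- c(0, s, c_, d)
  for (t in seq_len(horizon)) {
    i_eff <- i[t] * (1 - pf[t])
    new_cases <- s * i_eff
    deaths <- c_ * f[t]
    remitted <- c_ * r[t]
    s2 <- s - new_cases + remitted
    c2 <- c_ + new_cases - deaths - remitted
    if (s2 < -1e-12 || c2 < -1e-12) {
      abort(paste(
        "Negative state occupancy: rates too large for an annual cycle.",
        "Check that incidence, case fatality and remission are annual",
        "probabilities, not multi-year cumulative risks."
      ))
    }
    s <- max(0, s2); c_ <- max(0, c2); d <- d + deaths
    out[t + 1, ] <- c(t, s, c_, d)
  }
  tibble::as_tibble(out) |>
    dplyr::mutate(
      prevalence = ifelse(.data$well + .data$case > 0,
                          .data$case / (.data$well + .data$case), 0),
      # disease contribution to all-cause mortality in the upcoming cycle
      mortality_rate = .data$prevalence * f[pmin(.data$year + 1, horizon)]
    ) |>
    dplyr::select("year", "well", "case", "dead_disease", "prevalence",
                  "mortality_rate")
}

# ---------------------------------------------------------------------------
# lifetable engine internals: fast matrix representation of the inputs

prep_pmslt <- function(epi, max_age = NULL) {
  stopifnot(inherits(epi, "epi_inputs") || is.list(epi))
  max_age <- max_age %||% max(epi$mortality$age)
  sexes <- c("female", "male")
  ages <- 0:max_age
  need <- tidyr::expand_grid(sex = sexes, age = ages)
  have <- dplyr::semi_join(need, epi$mortality, by = c("sex", "age"))
  if (nrow(have) != nrow(need)) {
    abort("Mortality table must cover every single year of age for both sexes.")
  }
  q <- matrix(0, max_age + 1, 2, dimnames = list(NULL, sexes))
  for (s in sexes) {
    m <- epi$mortality[epi$mortality$sex == s, ]
    q[m$age + 1, s] <- m$rate
  }

  diseases <- unique(epi$disease_epi$disease)
  rate_mat <- function(col) {
    lapply(setNames(diseases, diseases), function(d) {
      mt <- matrix(0, max_age + 1, 2, dimnames = list(NULL, sexes))
      sub <- epi$disease_epi[epi$disease_epi$disease == d, ]
      sub <- sub[sub$age <= max_age, ]
      mt[cbind(sub$age + 1, match(sub$sex, sexes))] <- sub[[col]]
      mt
    })
  }
  inc <- rate_mat("incidence")
  cf <- rate_mat("case_fatality")
  rem <- rate_mat("remission")
  prev0 <- rate_mat("prevalence")

  uc <- epi$unit_costs[match(diseases, epi$unit_costs$disease), ]
  dw <- setNames(uc$disability_weight, diseases)

  yld <- numeric(max_age + 1)
  bm <- epi$background_morbidity[epi$background_morbidity$age <= max_age, ]
  yld[bm$age + 1] <- bm$yld_rate

  # exposure: per risk factor a (stratum x category) prevalence matrix
  bands_tbl <- epi$exposure |>
    dplyr::distinct(.data$age_lo, .data$age_hi) |>
    dplyr::arrange(.data$age_lo)
  n_bands <- nrow(bands_tbl)
  band_of_age <- rep(n_bands, max_age + 1)
  for (b in rev(seq_len(n_bands))) {
    band_of_age[ages >= 0 & ages <= bands_tbl$age_hi[b]] <- b
  }
  band_of_age[ages < bands_tbl$age_lo[1]] <- 1

  strata <- tidyr::expand_grid(sex = sexes, band = seq_len(n_bands))
  stratum_idx <- function(sex_i, age) {
    (sex_i - 1) * n_bands + band_of_age[age + 1]
  }

  rfs <- unique(epi$exposure$risk_factor)
  expo <- lapply(setNames(rfs, rfs), function(rf) {
    sub <- epi$exposure[epi$exposure$risk_factor == rf, ]
    cats <- sub |>
      dplyr::distinct(.data$category, .data$lower, .data$upper) |>
      dplyr::arrange(.data$lower)
    p <- matrix(0, nrow(strata), nrow(cats))
    for (k in seq_len(nrow(strata))) {
      rows <- sub[sub$sex == sexes[ceiling(k / n_bands)] &
                    sub$age_lo == bands_tbl$age_lo[(k - 1) %% n_bands + 1], ]
      p[k, ] <- rows$prevalence[match(cats$category, rows$category)]
    }
    rr_sub <- epi$rr[epi$rr$risk_factor == rf, ]
    rr_by_disease <- lapply(setNames(diseases, diseases), function(d) {
      rd <- rr_sub[rr_sub$disease == d, ]
      if (nrow(rd) == 0) return(NULL)
      rd$rr[match(cats$category, rd$category)]
    })
    list(p = p, lower = cats$lower, upper = cats$upper, rr = rr_by_disease)
  })

  cohorts <- epi$population |>
    dplyr::filter(.data$age <= max_age, .data$persons > 0) |>
    dplyr::mutate(sex_i = match(.data$sex, sexes))

  list(
    max_age = max_age, sexes = sexes, q = q, diseases = diseases,
    inc = inc, cf = cf, rem = rem, prev0 = prev0, dw = dw,
    cost_basis = setNames(uc$cost_basis, diseases), yld = yld,
    expo = expo, n_bands = n_bands, band_of_age = band_of_age,
    n_strata = nrow(strata), stratum_idx = stratum_idx, cohorts = cohorts
  )
}

# combined PIF matrix [stratum, disease] for one year's shift vector
pif_matrix <- function(prep, deltas) {
  pif <- matrix(0, prep$n_strata, length(prep$diseases),
                dimnames = list(NULL, prep$diseases))
  for (rf in names(deltas)) {
    d <- deltas[[rf]]
    ex <- prep$expo[[rf]]
    if (is.null(ex) || abs(d) < 1e-12) next
    m <- shift_transfer_matrix(ex$lower, ex$upper, d)
    p_new <- ex$p %*% m
    for (dis in prep$diseases) {
      rr <- ex$rr[[dis]]
      if (is.null(rr)) next
      denom <- as.vector(ex$p %*% rr)
      num <- denom - as.vector(p_new %*% rr)
      k <- 1 - (1 - pif[, dis]) * (1 - num / denom)
      pif[, dis] <- k
    }
  }
  pif
}

# one scenario pass: annual cycles vectorised over cohorts and diseases.
# pif_fun(t) must return the [stratum, disease] PIF matrix for cycle t
# (t = 1 is the first year after baseline). m_base: baseline disease
# mortality [cohort, disease, t] used to anchor the all-cause adjustment.
run_scenario <- function(prep, pif_fun, discount_rate, m_base = NULL) {
  co <- prep$cohorts
  nc <- nrow(co)
  nd <- length(prep$diseases)
  horizon <- prep$max_age - min(co$age)
  l <- rep(1, nc)
  S <- C <- D <- matrix(0, nc, nd)
  for (j in seq_len(nd)) {
    p0 <- prep$prev0[[j]][cbind(co$age + 1, co$sex_i)]
    C[, j] <- p0
    S[, j] <- 1 - p0
  }
  m_store <- array(0, c(nc, nd, horizon))
  case_years <- incident <- matrix(0, horizon, nd,
                                   dimnames = list(NULL, prep$diseases))
  h_disc <- 0
  ly_disc <- 0
  floored <- FALSE
  for (t in seq_len(horizon)) {
    age <- co$age + (t - 1)
    active <- age <= prep$max_age
    if (!any(active)) break
    idx <- cbind(pmin(age, prep$max_age) + 1, co$sex_i)
    pif_t <- pif_fun(t)
    str_i <- prep$stratum_idx(co$sex_i, pmin(age, prep$max_age))
    # disease mortality and states
    m_now <- matrix(0, nc, nd)
    prev <- matrix(0, nc, nd)
    for (j in seq_len(nd)) {
      alive_frac <- S[, j] + C[, j]
      prev[, j] <- ifelse(alive_frac > 0, C[, j] / alive_frac, 0)
      f <- prep$cf[[j]][idx]
      m_now[, j] <- f * prev[, j]
    }
    m_store[, , t] <- m_now
    base_m <- if (is.null(m_base)) m_now else m_base[, , t]
    q_adj <- prep$q[idx] + rowSums(m_now - base_m)
    if (any(q_adj < 0 & active)) floored <- TRUE
    q_adj <- pmin(1, pmax(0, q_adj))
    q_adj[!active] <- 1  # past the age cap: no further person-years
    L <- l * (1 - q_adj / 2) * active
    disab <- pmin(1, prep$yld[pmin(age, prep$max_age) + 1] +
                    as.vector(prev %*% prep$dw))
    disc <- 1 / (1 + discount_rate)^(t - 1)
    h_disc <- h_disc + disc * sum(co$persons * L * (1 - disab))
    ly_disc <- ly_disc + disc * sum(co$persons * L)
    for (j in seq_len(nd)) {
      case_years[t, j] <- sum(co$persons * L * prev[, j])
      alive_frac <- S[, j] + C[, j]
      i_eff <- prep$inc[[j]][idx] * (1 - pif_t[cbind(str_i, j)])
      new_share <- ifelse(alive_frac > 0, S[, j] * i_eff / alive_frac, 0)
      incident[t, j] <- sum(co$persons * l * new_share * active)
      deaths <- C[, j] * prep$cf[[j]][idx]
      remitted <- C[, j] * prep$rem[[j]][idx]
      new_cases <- S[, j] * i_eff
      S2 <- S[, j] - new_cases + remitted
      C2 <- C[, j] + new_cases - deaths - remitted
      if (any(S2 < -1e-12 | C2 < -1e-12)) {
        abort("Negative state occupancy in the lifetable disease process: annual rates too large.")
      }
      S[, j] <- pmax(0, S2)
      C[, j] <- pmax(0, C2)
      D[, j] <- D[, j] + deaths
      tot <- S[, j] + C[, j] + D[, j]
      if (any(abs(tot - 1) > 1e-9)) {
        abort("Disease-state conservation violated (well + case + dead != 1).")
      }
    }
    l <- l * (1 - q_adj)
  }
  if (floored) {
    warn("Adjusted all-cause mortality fell below 0 in some strata; floored at 0.")
  }
  list(h_disc = h_disc, ly_disc = ly_disc, case_years = case_years,
       incident = incident, m = m_store, horizon = horizon)
}

#' Run the proportional multi-state lifetable
#'
#' The population health engine: risk-factor shifts (decaying at 50% per
#' annum) move categorical exposure distributions, potential impact
#' fractions scale disease incidence, parallel three-state disease
#' processes (well/case/dead) feed their mortality changes back into
#' all-cause mortality, and years of life lived are adjusted for disease
#' and background disability. DALYs averted is the discounted difference in
#' health-adjusted life-years between the intervention and comparator
#' scenarios, summed over the adult cohorts' remaining lifetimes (ages
#' capped at 100 by default).
#'
#' Background (secular) trends, when supplied, are added to the exposure
#' inputs of both scenarios and decay at the same rate, so only
#' intervention-attributable differences drive the DALY estimate.
#'
#' @param epi An `epi_inputs` object ([generate_epi_inputs()] or
#'   [read_epi_inputs()]).
#' @param shifts Tibble with `risk_factor` and `delta0`: the initial
#'   additive change in each continuous exposure (BMI units, mg sodium,
#'   g fruit, g vegetables). Risk factors not listed are unshifted.
#' @param background Optional tibble in the same form: secular trend
#'   applied to both scenarios.
#' @param decay_rate Annual exponential decay of all shifts; default 0.5.
#' @param discount_rate Annual discount rate for health outcomes;
#'   default 0.03.
#' @param max_age Age cap; default the oldest age in the mortality table.
#' @return A `pmslt_result` object: list with `dalys_averted`,
#'   `case_year_deltas` (per disease and year: `delta_case_years`,
#'   `delta_incident_cases`, undiscounted), `h_comparator`,
#'   `h_intervention` (discounted health-adjusted life-years) and the
#'   shift/decay settings.
#' @export
run_lifetable <- function(epi, shifts, background = NULL,
                          decay_rate = 0.5, discount_rate = 0.03,
                          max_age = NULL) {
  engine <- pmslt_engine(epi, background = background,
                         decay_rate = decay_rate,
                         discount_rate = discount_rate, max_age = max_age)
  engine$eval(shifts)
}

#' Reusable lifetable engine
#'
#' Prepares the lifetable inputs and the comparator scenario once, and
#' returns an evaluator that scores intervention shift sets against them.
#' This is what makes Monte Carlo uncertainty analysis affordable: only the
#' intervention scenario is recomputed per draw. [run_lifetable()] is the
#' one-shot wrapper.
#'
#' @inheritParams run_lifetable
#' @return List with `eval(shifts)` returning a `pmslt_result`, plus the
#'   prepared internals.
#' @export
pmslt_engine <- function(epi, background = NULL, decay_rate = 0.5,
                         discount_rate = 0.03, max_age = NULL) {
  prep <- prep_pmslt(epi, max_age)
  rf_names <- names(prep$expo)
  bg0 <- setNames(rep(0, length(rf_names)), rf_names)
  if (!is.null(background) && nrow(background) > 0) {
    unknown <- setdiff(background$risk_factor, rf_names)
    if (length(unknown) > 0) {
      abort(paste0("Unknown risk factor(s) in `background`: ",
                   paste(unknown, collapse = ", ")))
    }
    bg0[background$risk_factor] <- background$delta0
  }

  zero_pif <- matrix(0, prep$n_strata, length(prep$diseases),
                     dimnames = list(NULL, prep$diseases))
  make_pif_fun <- function(d0) {
    cache <- vector("list", prep$max_age + 2)
    if (all(d0 == 0)) return(function(t) zero_pif)
    function(t) {
      if (all(abs(d0) * (1 - decay_rate)^(t - 1) < 1e-10)) return(zero_pif)
      if (!is.null(cache[[t]])) return(cache[[t]])
      res <- pif_matrix(
        prep, lapply(setNames(as.list(d0), names(d0)),
                     function(x) decay_effect(x, t - 1, decay_rate))
      )
      cache[[t]] <<- res
      res
    }
  }

  base_run <- run_scenario(prep, function(t) zero_pif, discount_rate)
  comp_run <- if (all(bg0 == 0)) {
    base_run
  } else {
    run_scenario(prep, make_pif_fun(bg0), discount_rate, m_base = base_run$m)
  }

  eval_shifts <- function(shifts) {
    delta0 <- setNames(rep(0, length(rf_names)), rf_names)
    if (!is.null(shifts) && nrow(shifts) > 0) {
      unknown <- setdiff(shifts$risk_factor, rf_names)
      if (length(unknown) > 0) {
        abort(paste0("Unknown risk factor(s) in `shifts`: ",
                     paste(unknown, collapse = ", ")))
      }
      delta0[shifts$risk_factor] <- shifts$delta0
    }
    int_run <- if (all(delta0 == 0)) {
      comp_run
    } else {
      run_scenario(prep, make_pif_fun(bg0 + delta0), discount_rate,
                   m_base = base_run$m)
    }
    deltas <- tibble::tibble(
      disease = rep(prep$diseases, each = int_run$horizon),
      year = rep(seq_len(int_run$horizon) - 1, length(prep$diseases)),
      delta_case_years = as.vector(int_run$case_years - comp_run$case_years),
      delta_incident_cases = as.vector(int_run$incident - comp_run$incident),
      cost_basis = rep(unname(prep$cost_basis[prep$diseases]),
                       each = int_run$horizon)
    )
    structure(
      list(
        dalys_averted = int_run$h_disc - comp_run$h_disc,
        h_comparator = comp_run$h_disc,
        h_intervention = int_run$h_disc,
        life_years_comparator = comp_run$ly_disc,
        life_years_intervention = int_run$ly_disc,
        case_year_deltas = deltas,
        shifts = delta0, background = bg0,
        decay_rate = decay_rate, discount_rate = discount_rate
      ),
      class = "pmslt_result"
    )
  }

  list(eval = eval_shifts, prep = prep, base_run = base_run,
       comp_run = comp_run, background = bg0,
       decay_rate = decay_rate, discount_rate = discount_rate)
}

#' @export
print.pmslt_result <- function(x, ...) {
  cat("<pmslt_result>\n")
  cat("  DALYs averted (discounted):", format(x$dalys_averted, digits = 4),
      "(negative = net health loss)\n")
  nz <- x$shifts[x$shifts != 0]
  if (length(nz) > 0) {
    cat("  risk-factor shifts:",
        paste(names(nz), format(nz, digits = 3), collapse = ", "), "\n")
  } else {
    cat("  null scenario (no risk-factor shift)\n")
  }
  invisible(x)
}

#' @rdname run_lifetable
#' @param x A `pmslt_result` object.
#' @param ... Unused.
#' @export
tidy.pmslt_result <- function(x, ...) {
  x$case_year_deltas
}

#' @rdname run_lifetable
#' @export
glance.pmslt_result <- function(x, ...) {
  tibble::tibble(
    dalys_averted = x$dalys_averted,
    h_comparator = x$h_comparator,
    h_intervention = x$h_intervention,
    decay_rate = x$decay_rate,
    discount_rate = x$discount_rate
  )
}
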