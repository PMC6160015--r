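# Individual-level microsimulation oracle for the proportional lifetable.
#
# Simulates n_sim individuals through annual cycles under the same model
# assumptions as the cohort lifetable: disease state moves well -> case with
# probability i * (1 - PIF(t)); death occurs with probability
# q_other(a, t) + case_fatality * I(case at year start), where q_other
# anchors the scenario to the comparator's simulated prevalence so the
# comparator's expected all-cause mortality equals the input q. Health-
# adjusted contribution per year: (1 - yld - dw * I(case)) discounted, a
# full year if the individual survives the cycle and half a year if they
# die during it. Both scenarios share the same uniform draws (common random
# numbers), so the variance of the estimated DALY difference is small.
#
# Returns simulated discounted health-adjusted life-years per scenario and
# the Monte Carlo SEs, scaled to the cohort sizes of `epi$population`.
microsim_oracle <- function(epi, delta0, decay_rate = 0.5,
                            discount_rate = 0.03, n_sim = 1e5, seed = 99) {
  pop <- epi$population
  max_age <- max(epi$mortality$age)
  n_per <- round(n_sim * pop$persons / sum(pop$persons))
  start_age <- rep(pop$age, n_per)
  n <- length(start_age)
  horizon <- max_age - min(pop$age)

  de <- epi$disease_epi[epi$disease_epi$sex == "female", ]
  q_tab <- epi$mortality[epi$mortality$sex == "female", ]
  q_of <- function(a) q_tab$rate[match(pmin(a, max_age), q_tab$age)]
  i_of <- function(a) de$incidence[match(pmin(a, max_age), de$age)]
  f_of <- function(a) de$case_fatality[match(pmin(a, max_age), de$age)]
  p0_of <- function(a) de$prevalence[match(pmin(a, max_age), de$age)]
  yld_of <- function(a) {
    epi$background_morbidity$yld_rate[
      match(pmin(a, max_age), epi$background_morbidity$age)]
  }
  dw <- epi$unit_costs$disability_weight[1]

  set.seed(seed)
  u_init <- runif(n)
  u_death <- matrix(runif(n * horizon), n, horizon)
  u_inc <- matrix(runif(n * horizon), n, horizon)

  run <- function(pif_vec, prev_comp = NULL) {
    alive <- rep(TRUE, n)
    case <- u_init < p0_of(start_age)
    h <- numeric(n)
    prev_hat <- matrix(NA_real_, length(unique(start_age)), horizon)
    cohort_id <- match(start_age, sort(unique(start_age)))
    for (t in seq_len(horizon)) {
      age <- start_age + (t - 1)
      active <- alive & age <= max_age
      for (cid in seq_len(nrow(prev_hat))) {
        sel <- active & cohort_id == cid
        prev_hat[cid, t] <- if (any(sel)) mean(case[sel]) else 0
      }
      anchor <- if (is.null(prev_comp)) prev_hat[, t] else prev_comp[, t]
      q_other <- q_of(age) - f_of(age) * anchor[cohort_id]
      p_death <- pmin(1, pmax(0, q_other + f_of(age) * case))
      dies <- u_death[, t] < p_death & active
      disc <- 1 / (1 + discount_rate)^(t - 1)
      hw <- (1 - pmin(1, yld_of(age) + dw * case)) * ifelse(dies, 0.5, 1)
      h <- h + disc * hw * active
      i_eff <- i_of(age) * (1 - pif_vec[t])
      new_case <- !case & u_inc[, t] < i_eff
      case <- case | new_case
      alive <- alive & !dies
    }
    list(h = h, prev_hat = prev_hat)
  }

  pif_comp <- rep(0, horizon)
  pif_int <- tiny_pif(decay_effect(delta0, seq_len(horizon) - 1, decay_rate))

  comp <- run(pif_comp)
  int <- run(pif_int, prev_comp = comp$prev_hat)

  scale <- sum(pop$persons)
  per_cap_w <- rep(pop$persons / n_per, n_per) / sum(pop$persons) * n
  wmean <- function(x) mean(x * per_cap_w)
  wse <- function(x) sd(x * per_cap_w) / sqrt(n)
  d_h <- int$h - comp$h
  list(
    h_comp = scale * wmean(comp$h), se_comp = scale * wse(comp$h),
    h_int = scale * wmean(int$h), se_int = scale * wse(int$h),
    dalys = scale * wmean(d_h), se_dalys = scale * wse(d_h)
  )
}
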