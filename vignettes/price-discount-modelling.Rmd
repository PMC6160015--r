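---
title: "Modelling the health and economic consequences of food price discounts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health and economic consequences of food price discounts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pricehealth)
```

`pricehealth` evaluates what a 20% price discount on healthy food and
beverage lines, trialled in remote Indigenous Australian community
stores, did to population health and to health-sector and retail costs.
This vignette is the package's account of its models: the assumptions,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations.

## From store sales to dietary change

The trial's upstream statistical analysis (a stepped-wedge mixed model of
weekly store sales, out of scope here) delivers *percent* changes, with
95% CIs, in each of the printed food and beverage categories relative to
a 49-week pre-trial baseline. The package takes those as inputs and works
in both directions:

* `absolute_from_percent()` multiplies the mean baseline value of a
  category and metric (weight g/person/day, energy MJ/person/day, sodium
  mg/person/day) by the percent change; both CI bounds scale identically.
* `percent_from_absolute()` is the exact inverse; the round trip is the
  identity to 1e-12 relative error (a tested invariant).

Price elasticities are **arc-style ratios of percent changes**, not
log-log regressions: the percent quantity change over the 24-week
discount period divided by the magnitude of the percent price change
(20), signed so that a quantity rise under a price fall is positive.
This form is forced by how the published elasticity table is defined and
is confirmed arithmetically: recomputing from the baseline diet and the
discount-only arm's during-period absolute changes reproduces the printed
per-1% elasticities for 15 of 23 categories exactly at the printed
rounding, including all of the statistically significant ones (cereals
0.55, fresh fruit 0.95, fresh+frozen vegetables 0.44, total diet 0.32).
The remaining small-baseline categories (beef, pork, fruit other, water,
...) differ in the second decimal because the published table was
computed from unrounded trial estimates; the package does not force
agreement there. The same reasoning identifies the *discount-only* arm as
the one behind the published table: only that arm's numbers reproduce it.

Totals are handled with care: the total row carries its own
trial-supplied CI; when a total must be built from categories (grouped
rows such as "all fruit + vegetables"), means are summed and CI
half-widths are combined in quadrature under an independence assumption,
and percent changes for groups are always computed *after* summing the
absolute changes.

Display rounding throughout is half-away-from-zero (`round_half_up()`),
1 d.p. for grams and 2 d.p. for elasticities, because banker's rounding
does not reproduce the printed tables; internal computation keeps full
precision.

## Energy to BMI

A sustained percent change in dietary energy intake maps linearly to a
population mean BMI change through energy-flux coefficients for adults
and children, weighted by the community structure (59% adults, 41%
children) and assumed sustained for 12 months:

delta BMI = %ΔE × (f_adult·c_adult + f_child·c_child) × duration.

The literature coefficient values are not part of the package's inputs;
they are mandatory configuration. The shipped default is a **calibration,
not a literature value**: the pooled coefficient
(`default_energy_bmi_coef()`, 0.1715 BMI units per 1% sustained energy
change) that maps the discount-only arm's during-period energy change
(+0.57 MJ on an 8.5 MJ baseline, +6.71%) to its reported BMI change of
+1.15 units. As a check, that single calibrated constant predicts the
combined arm's reported +1.89 BMI units from its +0.92 MJ to within 0.05.
CI bounds are propagated through the same linear map; the original
analysis reports wider, asymmetric BMI intervals, suggesting Monte Carlo
propagation with uncertain coefficients whose exact distribution is
unstated — a known divergence.

## The proportional multi-state lifetable

Health outcomes come from a cohort Markov model of the adult trial
population (about 5,000 adults, closed cohort, ages capped at 100).

**Exposures are categorical.** Each risk factor (BMI, sodium, fruit,
vegetables) is a banded distribution by age band and sex, piecewise
uniform within bands. An intervention shift is an additive translation of
the underlying continuous exposure, re-binned onto the original bands
(`shift_distribution()`); mass pushed past the finite end caps is clamped
into the extreme band with a warning. Categorical exposure makes the
potential impact fraction an exact finite sum — brute-forceable in tests —
at the price of within-band resolution.

**Potential impact fractions** follow the comparative-risk-assessment
formula PIF = (Σ pRR − Σ p'RR)/Σ pRR, per stratum and disease. Multiple
risk factors acting on one disease combine multiplicatively,
1 − PIF_tot = Π(1 − PIF_k); whether the original analysis combined
pathways this way is unstated, and multiplicative combination was chosen
as the standard assumption when joint exposure data are absent.

**Sodium** is linked to IHD, stroke and hypertensive heart disease
through a per-100 mg log-linear relative risk evaluated at band midpoints
(reference band RR = 1), a deliberate simplification: the original
pathway runs sodium → blood pressure → disease, but its functional form
is not given, and an unparameterised blood-pressure sub-model would add
nothing testable.

**Effect decay.** Dietary behaviour change erodes; every shift decays
exponentially at 50% per annum (`decay_effect()`), so 3.1% of the initial
effect remains after five years. Background secular trends, when
configured, decay at the same rate and are added to the exposure inputs
of *both* scenarios, so only intervention-attributable differences drive
the DALY estimate (a tested invariant: background alone yields exactly
zero DALYs averted).

**Disease dynamics** are annual-cycle difference equations on
proportions, per cohort and disease: well → case at incidence × (1 −
PIF(t)), case → dead-from-disease at the case fatality rate, case → well
at the remission rate (zero by default). The closed-form continuous-time
solution of the three-state model was deliberately not used: annual
difference equations are simpler, their step-size adequacy is asserted by
a conservation invariant (well + case + dead = 1 to 1e-9 at every cycle),
and they can be validated against an individual-level microsimulation.
Rates too large for an annual cycle produce negative occupancies and
abort with an instruction to check the inputs.

**Mortality feedback.** Disease mortality among the living is case
fatality × prevalence. Scenario all-cause mortality is the input
mortality plus the scenario-minus-baseline difference in summed disease
mortality, floored at zero with a warning. Person-years use the trapezoid
rule L = l·(1 − q/2); years are weighted by 1 − (background
disability + Σ disability_weight × prevalence), capped at 1, and
discounted at 3% per year. DALYs averted is the discounted difference in
health-adjusted life-years, intervention minus comparator — negative
means net health loss. The engine also returns per-disease, per-year
case-year and incident-case deltas for costing.

**Validation.** On a three-age, one-disease instance, the cohort
lifetable agrees with an independent 100,000-individual microsimulation
(common random numbers across scenarios) within 3 Monte Carlo standard
errors on DALYs averted, and within 0.5% on absolute health-adjusted
life-year levels — the residual being the proportional model's
independence assumption between disease state and other-cause death,
which the microsimulation does not impose on the half-year of life lost
in the year of death.

## Costs, offsets and the ICER

The intervention cost inventory is itemised (18 items across the
discount and education strategies, with person-hours where labour was
estimated). Ledger arithmetic is exact integer sums; the only division is
the per-arm split of pooled design costs (half each, rounded half away
from zero — which is why the printed inventory total exceeds the item sum
by one dollar) and per-store averages. Nominal 2012–14 dollars are
deflated to AUD2011 with a single CPI step, ×99.8/104.8; the factor is
4.77%, printed as 4.7% (truncated) in the source material, and the
package keeps full precision internally. Per-store averages are computed
on nominal totals, matching the published summary.

Treatment cost deltas value each disease's case-year delta (incident-case
delta for colon cancer) at its unit cost, multiplied by 1.19 — the
additional cost of treating Indigenous Australians, read as a 19% loading
rather than ×2.19 — and discounted per year of accrual at 3%. Net cost =
deflated intervention cost + treatment cost delta (negative deltas are
cost-offsets). `compute_icer()` reports net cost per DALY averted against
the $50,000/DALY Australian threshold, with *dominated* (costs more,
worse health) and *dominant* (saves money, better health) classified
before any ratio; a zero health effect with nonzero cost is `no_effect`.

## Uncertainty

`run_psa()` draws each declared input from its family — normal for trial
percent changes (SE = CI half-width / 1.96), lognormal for relative
risks, gamma for costs, `fixed` for degenerate point values — evaluates
the deterministic pipeline per draw, and summarises with **empirical
2.5/97.5 percentiles** (linear interpolation), the non-parametric choice,
since no parametric interval method dominates. Failed iterations are
excluded and reported rather than resampled (resampling would invisibly
bias summaries toward benign draws); more than 1% failures aborts. Which
parameters are sampled is entirely configuration-driven because the
original analysis does not state its sampled set (its cost inventory is
point-valued yet its net costs carry uncertainty intervals). The
pipeline's default samples the four risk-factor shifts from their trial
CIs. Quadrant fractions of the (DALYs averted, net cost) plane are
reported; `autoplot()` draws the plane.

## The synthetic epidemiology

The original model was populated from national and Indigenous-specific
sources whose tabulated values are not reproduced in the trial report, so
the package generates structurally equivalent inputs
(`generate_epi_inputs()`): Gompertz-shaped all-cause mortality by single
year of age and sex (forced monotone above age 60), logistic-in-age
disease incidence in the single-digits-per-1000 range rising steeply with
age, case fatality growing from mid-life, prevalence near incidence ×
mean duration, Dirichlet-style exposure prevalence normalised exactly to
1 per stratum, band relative risks anchored at 1 in the reference
category (harmful above-reference bands for BMI and sodium, protective
gradients for fruit and vegetables), gamma-perturbed unit treatment
costs, and an exponentially declining adult age structure scaled to the
trial's 5,024 adults. All draws flow from one integer seed; identical
seeds give bit-identical sets.

What it does **not** emulate: actual Northern Territory Indigenous
epidemiology (no claim of matching any measured rate), demographic
change, migration, correlated risk factors, or secular disease trends.
Consequently passing tests demonstrate the *mechanics* — invariants,
directions, orders of magnitude, internal consistency — not the published
DALY or net-cost point estimates, which are unattainable without the
original input tables. Runs against measured data use the same CSV
schemas via `read_epi_inputs()`.

A companion generator, `generate_sales_series()`, produces weekly
per-category sales (49 baseline + 24 discount + 24 follow-up weeks,
52-week sinusoidal seasonality, optional secular slope, multiplicative
noise, a fractional discount-phase step) used to demonstrate that the
diet-response stage recovers injected effects; recovery is a simple
mean-ratio estimator, since the trial's own mixed model is out of scope.

## Numerical choices and problem sizes

* Annual cycles; trapezoid person-years; discounting by whole years from
  the intervention start.
* PIF computation short-circuits once the decayed shift falls below
  1e-10 (the geometric decay makes effects numerically zero within ~35
  years), and per-year PIF matrices are cached, which is what makes the
  2000-iteration Monte Carlo affordable (the comparator is computed once
  per configuration; only the intervention scenario is re-run per draw —
  `pmslt_engine()`).
* Degenerate inputs: zero shifts short-circuit to the comparator run,
  guaranteeing *exactly* zero DALYs averted under the null rather than
  zero-within-tolerance.
* Test problem sizes were chosen to exercise every pathway at high
  precision while keeping the suite quick: the microsimulation oracle
  uses 100,000 individuals on a three-age instance; percentile-machinery
  checks use 2000 draws; pipeline determinism checks use 25–40 draws.

## Known limitations

* DALY and cost magnitudes on synthetic inputs are illustrative only.
* Child health is not modelled (children affect only the BMI weighting),
  and there is no breast-cancer pathway; diabetes "sequelae" are a single
  state whose disability weight can be inflated in configuration.
* BMI uncertainty propagation is linear, narrower than the original
  report's intervals.
* The sodium pathway bypasses blood pressure; the per-100 mg RR absorbs
  that link.
* Elasticities are arc ratios at a single 20% price change; no demand
  system or cross-price matrix is estimated.
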