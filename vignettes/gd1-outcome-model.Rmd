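---
title: "Modelling long-term outcomes of treated Gaucher disease type 1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term outcomes of treated Gaucher disease type 1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gd1markov)
```

## The modelling problem

Gaucher disease type 1 (GD1) is a rare lysosomal storage disorder whose
burden spans hematologic, visceral and skeletal manifestations. The DS3
severity score summarizes these domains on a 0–19 scale, and treated
patients move both up *and* down that scale over years of enzyme
replacement or substrate reduction therapy. `gd1markov` implements a
published modelling framework that turns DS3 severity into a Markov
cohort model: nine ranked alive health states, regression-derived state
utilities, ordered-logit annual transition probabilities, a calibrated
disease-specific mortality curve, and an annual-cycle cohort engine that
reports quality-adjusted life years (QALYs) and the share of remaining
lifetime spent in each state.

The nine states cross the DS3 severity band (mild, moderate, marked,
severe) with bone involvement. Bone pain (BP) is distinguished from
severe skeletal complications (SSC: lytic lesions, avascular necrosis,
fracture) only within the mild band; the other bands distinguish only
the presence of SSC. Ranks 1–9 order the states from least to most
severe, and that ordering is the outcome scale of the transition
regression. Death is an absorbing state handled by the mortality module,
deliberately outside the ordinal scale.

```{r}
health_states()
```

## Health-state utilities

Utilities come from a linear (identity-link) regression of EQ-5D
utilities on severity contrasts, bone pain, SSC, sex and age at
treatment initiation, estimated by GEE to respect repeated observations
per patient. Predictions use the method of recycled predictions: state
indicators are fixed at each state's values and the remaining covariates
averaged over the estimation sample. With an identity link the
prediction at the covariate means (69.1% female, mean age 53.9) equals
the mean of per-subject predictions, which is what
`estimation_profile()` encodes. One prediction rule matters: the
bone-pain effect is included for every SSC-containing state, not just
the mild-with-BP state, so the SSC states differ from their non-SSC
partners by the sum of the bone-pain and SSC coefficients (−0.080).

```{r}
round(utility_table(default_utility_coefficients()), 3)
```

**Age-coefficient calibration.** The published age coefficient is
printed as −0.002 with 95% CI (−0.004, 0.001). At exactly −0.002 the
mild and severe-with-SSC predictions are 0.738 and 0.490, which are
inconsistent with the published endpoint values of 0.76 and 0.52. Since
the printed value is rounded, the package defaults to −0.0015 — inside
the CI and rounding to the printed value — which reproduces both
endpoints to well under 0.01. The exactly-as-printed value remains
available via `default_utility_coefficients("printed")`. The Markov
engine always evaluates utilities at the estimation-sample means rather
than the simulated cohort's own age/sex mix: the published lifetime
results are consistent with the former (the undiscounted QALYs-to-life-
years ratio matches the recycled-prediction utilities), and keeping the
utility scale fixed makes cohorts comparable.

Utilities are never censored at 0 or 1; a warning is raised if a
prediction leaves that interval, which the default inputs never trigger.

## Annual transition probabilities

Transitions follow a proportional-odds (ordered logistic) model: the
next-year state rank depends on the previous-year state (contrasts for
ranks 2–9 against mild), years on treatment (second year, third-plus
year against the first), the DS3 severity category at treatment start,
and splenectomy status. The cumulative parameterization is
`P(rank <= k) = plogis(cutpoint_k − lp)`, the standard convention in
which a *larger* linear predictor pushes probability toward *worse*
states. Two checks pin the sign convention down: previous-state
contrasts increase with severity, and the negative coefficient for an
intact spleen makes improvement more likely for non-splenectomized
patients, both matching the published direction.

All covariates are categorical, so each of the 24 combinations of
treatment duration (3) × baseline severity (4) × spleen status (2)
yields one 9 × 9 matrix whose rows are the next-state distributions;
with covariates fixed within a combination, the recycled prediction
coincides with the direct prediction. Rows sum to one by construction,
and `all_matrices()` materializes the full set:

```{r}
mats <- all_matrices()
round(mats[["T1_Dmild_intact"]][1:3, 1:4], 4)
```

Conventions adopted where the published description is silent:

* **Treatment-duration clamping.** Cycle 1 uses the first-year matrix,
  cycle 2 the second-year matrix, and all later cycles the third-plus
  matrix.
* **Baseline severity of SSC start states.** A cohort starting in
  "marked with SSC" has baseline category *marked*: the baseline
  covariate is the severity band, not the bone status.
* **Proportional odds is taken as-is.** The source analysis noted the
  proportional-odds assumption was not fully satisfied but used the
  model anyway because sparse data ruled out less restrictive
  alternatives; this package does not add a partial-proportional
  extension.

## Mortality

Disease-specific mortality is a Gompertz hazard `a·exp(b·age)` whose
annual death probability integrates the hazard over each year of age.
The published summary data pin down exactly two quantities — life
expectancy at birth of 68 years, and 42.29 remaining years at the
cohort start age of 32 — so the two Gompertz parameters are calibrated
jointly to those targets by a damped Newton iteration on
`(log a, log b)` with a central-difference Jacobian (convergence
tolerance 10⁻⁶ years, bounded iterations, residuals reported on
failure). Because a Gompertz fitted to disease summaries understates
old-age mortality, the model uses at every age the *maximum* of the
disease-specific and general-population death probabilities; with the
default inputs the general table overtakes the disease curve in the
70s, consistent with the published account. Life expectancy uses a
half-interval convention (`e(x) = 0.5 + Σ S(x, t)`), deliberately
mirroring the Markov engine's half-cycle correction so the engine's
life-years equal the curve's life expectancy by construction.

One overall curve (e0 = 68) serves all cohorts: the published lifetime
table states that every cohort has the same 42.29 remaining life years,
which is incompatible with spleen-stratified mortality. The
spleen-specific life expectancies (64/72) remain available as
alternative calibration targets via `gd1_mortality(e0 = ...)`.

The packaged general-population table is *synthetic*: a
Gompertz–Makeham hazard (A = 2.2e−4, B = 1.1e−5, C = 0.105 per year)
chosen to give a life expectancy at birth near the UK norm of about 81
years, tabulated over ages 0–110 with terminal probability 1. Any real
life-table export with the same `(age, qx)` CSV schema can be
substituted. The maximum modelled age of 110 is a cohort-extinction
bound; occupancy beyond the observed human life-table range is
negligible.

## The cohort engine

`run_cohort()` starts the whole cohort in one state at age 32 (by
default) and iterates annual cycles: death first, applied uniformly
across alive states at the age-specific probability — mortality depends
on age and calibration targets, not on the current health state, because
the published framework ties mortality to summary survival data rather
than to DS3 level — then survivors redistribute by the transition matrix
for the scenario's baseline severity and spleen status. Baseline
severity and spleen status are fixed for life (no splenectomy occurs
after treatment start). Death-before-transition versus the reverse
ordering differs only at order `q·Δp` and is not distinguishable from
the published description; the chosen order is fixed and documented.
The default horizon runs through the year beginning at age 110, whose
death probability of 1 extinguishes the cohort.

QALYs apply a half-cycle correction — each cycle contributes the
utility-weighted mean of its start and end occupancy — and discounting
at 3.5% per annum uses start-of-cycle exponents: cycle *t* is divided by
`(1 + r)^(t−1)`, so the first model year is undiscounted. Both
conventions are common in annual-cycle cohort models built in
spreadsheets; this package adopts the start-of-cycle variant because it
is the one consistent with the published discounted totals (the
end-of-cycle variant understates them by about 4%, far outside the
rounding of the inputs). `occupancy_shares()` normalizes half-cycle
person-years per state by total person-years alive.

A structural invariant worth knowing: transitions only move mass among
alive states, so `life_years()` equals `life_expectancy()` at the start
age for *any* row-stochastic transition matrices. The test suite asserts
this over random matrices, and it is why every cohort reports identical
life years.

**Reproduction scope.** With the default inputs the engine reproduces
the published intact-spleen lifetime results essentially exactly
(occupancy shares to within a few hundredths of a percentage point,
QALYs to well under 1%). The published *splenectomized* cohort results
are not reproducible from the printed transition coefficients under any
reading we examined: the printed spleen contrast of 1.089 log-odds
implies a far larger gap between the strata than the published table
shows for mild and moderate starting states, while the published
marked-with-SSC stratum gap is larger than mild/moderate's in a way no
single linear-predictor shift can produce. The package implements the
printed model; its splenectomized projections are internally consistent
with the printed coefficients and preserve the published *direction*
(intact cohorts accumulate more QALYs and more time in better states).

## Estimation

`fit_transition_model()` fits the proportional-odds model by maximum
likelihood (point estimation delegates to `MASS::polr`) and computes
cluster-robust (by patient) standard errors from the package's own
analytic per-observation scores: meat from per-cluster score sums,
bread from an observed information obtained by centrally differencing
the analytic score. The information is *not* taken from `polr`'s
finite-difference Hessian, which proved numerically unreliable when
cutpoints sit close together (adjacent rare categories). The package
also exposes `transition_loglik()`, a direct likelihood evaluation used
by the tests to verify the fit against brute-force arithmetic on small
panels.

`fit_utility_model()` implements the GEE with identity link and an
independence working correlation — the working structure is not stated
in the published analysis, and under the identity link this choice makes
the point estimates coincide with ordinary least squares while
cluster-robust standard errors (`sandwich::vcovCL`) carry the
within-patient correlation. The sample means of the female flag and age
are stored with the coefficients so recycled predictions use the right
averaging population.

Degenerate inputs fail loudly: a single observed outcome category, an
unobserved outcome rank (the 8-cutpoint layout would be unidentifiable),
unobserved predictor levels, fewer than two patients, and collinear
utility designs all raise diagnostic errors rather than returning
partial fits.

## The synthetic cohort generator

`simulate_panel()` and `simulate_utility_panel()` generate longitudinal
panels with the statistical structure the estimation routines assume,
emulating the source study's design: 133 treated adults by default,
annual state observations with follow-up drawn as a rounded
Normal(13.3, 6.1) clamped to [1, `n_years`]; baseline states
concentrated on the three most common starting states (19% mild, 28%
moderate, 28% marked with SSC, remainder uniform); 67.2% intact
spleens; baseline severity derived from the initial state; and sparse
utility observations (two per patient by default) with Gaussian noise
(sd 0.1) around the utility linear predictor, clipped to the UK EQ-5D
value-set floor of −0.594 (clipping counted and reported). Ages at
initiation are Normal(53.9, 15) clamped to 18–90, the instrument's
adult validation range; the age spread is a realism choice the source
summary does not constrain.

What the generator does *not* emulate: the 90-day matching window
between severity and quality-of-life instruments (panels are generated
pre-matched), missing visits and irregular observation spacing,
treatment switching or interruption, state-dependent mortality during
follow-up, and any misspecification of the proportional-odds form.
Passing parameter-recovery tests therefore demonstrates that the
estimation code inverts the assumed data-generating process, not that
the model is correctly specified for real registry data.

## Numerical choices and test scale

* Cutpoints are validated as nondecreasing; category probabilities are
  successive differences of the cumulative logistic with tiny negative
  rounding clamped to zero.
* Calibration: Newton tolerance 10⁻⁶ years, step halving to guarantee
  residual descent, explicit errors carrying residuals on failure or on
  a singular Jacobian (which arises only when the targets do not bind,
  e.g. targets equal to the general population's own life expectancy).
* Mass conservation in traces holds to 10⁻¹² per cycle and is asserted.
* Parameter-recovery tests run at 2,000 patients × up to 10 years
  (about 17,000 transitions) with a fixed seed, and the
  simulate–fit–project closure test compares truth-parameter and
  fitted-parameter lifetime projections at the same scale within 5%;
  these sizes keep the default suite fast while leaving Monte Carlo
  error well inside the asserted bands.

## Limitations

The framework models *treated* patients only — the source data contain
no untreated natural history — and excludes costs, adverse events,
treatment switching and probabilistic sensitivity analysis. The
proportional-odds assumption is inherited, not tested. Utilities derive
from an SF-36-to-EQ-5D mapping upstream of this package; the package
starts from utility-scale observations. The packaged life table is a
synthetic stand-in with the right schema and level, not an official
national table.
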