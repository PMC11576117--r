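---
title: "Modelling Huntington's disease progression and its societal cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Huntington's disease progression and its societal cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdprog)
```

## The model

Huntington's disease (HD) progresses irreversibly, but no single observed
score tracks the underlying biology: clinical instruments saturate, vary
between visits, and can even improve transiently while the disease does
not.  `hdprog` therefore models progression with a *progressive
continuous-time hidden Markov model* (CTHMM): a latent state sequence
`1 -> 2 -> ... -> ns` (the last state is death) evolving as a
continuous-time Markov chain with generator `Q`, where only the
`i -> i + 1` intensities `q_i` are non-zero — no skipping and no recovery.
The expected time spent in living state `i` (the mean sojourn time) is
`1 / q_i`.  Every patient starts in state 1 at birth (age 0).

Observations attach to this chain as four kinds of evidence:

* an artificial **birth** observation pinning state 1 at age 0;
* **visits** at irregular ages, each carrying a feature vector whose
  components are modelled as independent Gaussians given the state (one
  mean and standard deviation per state and feature);
* an **exact death** at a recorded age, contributing the density of
  entering the absorbing state at that instant (occupancy of the last
  living state times its exit rate);
* an **interval-censored death**, contributing the probability of
  absorption between the last visit and an upper bound.

The log-likelihood is the forward algorithm over each patient's ordered
events, with transition probabilities `expm(Q * dt)` over the gaps.
Because `Q` is progressive, `expm(Q * dt)` has a hypoexponential closed
form whose coefficients depend only on the rates; the compiled likelihood
precomputes them once per evaluation, which is what makes cross-validated
model selection affordable.

## Features: log transforms and grouped PCA

Twelve clinical scores per visit feed the model: three behavioural scores
(executive function, irritability/aggression, apathy), three functional
measures (a functional assessment score, total functional capacity (TFC),
and the independence scale), five cognitive tests (Stroop word/colour/
interference, symbol digit modality, categorical verbal fluency), and the
total motor score.  Skewed scores (the behavioural trio, the functional
assessment score, and the motor score) are mapped by `x -> log(1 + x)`;
the unit offset keeps zero scores finite.

The scores are reduced to two principal components by a *grouped* PCA:
visits are split into 10-year age brackets (configurable) and each bracket
is standardised and eigendecomposed separately, so that age-specific norms
do not masquerade as disease signal.  Loadings are sign-aligned across
groups (consecutive groups' matched components have non-negative dot
products) so scores are comparable across brackets.  Two further choices
matter and are this package's own:

* **Severity orientation.**  A principal axis has an arbitrary sign.  The
  pipeline pins it clinically: PC1 is flipped (in all groups together) so
  that the summed loading of the scores known to *decline* with HD
  (the five cognitive tests, TFC, independence) is negative — a higher PC1
  score always means a sicker visit.  Without this, about one cohort in
  six fitted a severity-inverted state labelling.
* **Monotone severity means.**  `fit_cthmm()` constrains the per-state
  emission means of PC1 to be non-decreasing in the state (via a
  log-increment reparameterisation).  The constraint contains the truth
  whenever PC1 is oriented as above, and it removes the label-permuted and
  state-collapsed local optima that otherwise trap quasi-Newton
  optimisation.  It can be disabled (`monotone = 0`).

The CTHMM treats features as conditionally independent given the state, so
the pipeline enforces low within-state correlation: after fitting, visits
are decoded with the Viterbi algorithm and Pearson correlations between
the PC scores are computed within each fitted state.  If any exceeds 0.2
in absolute value, the PCA is regrouped by fitted state and the loop
repeats (`iterative_fit()`).  One subtlety: a per-state PCA standardised
within state would erase all between-state signal, making the refit
unidentifiable.  Pearson correlation is translation-invariant, so the
regrouped projection keeps each state's loadings and scales but centres
every state at the pooled means (`fit_group_pca(center = "pooled")`) —
the within-state decorrelation guarantee is unchanged and the severity
separation survives.

## Life-expectancy bias correction

Only about 5% of patients have a recorded death age; everyone else is
right-censored at their last visit, typically after just a couple of years
of follow-up.  Fitted naively, the exit rate of the final living state is
then essentially unidentified and its sojourn time explodes (our
uncorrected fits give 30-120 years against a true 11.4).  The correction
gives every censored patient an interval-censored death between their last
visit and a single global artificial upper bound `U`, and calibrates `U`
by bisection so that the *implied mean age at death* — recorded deaths
plus interval midpoints — matches an external anchor, by default 63.9
years (an HD life-expectancy estimate from national cause-of-death
registry data).  The implied mean is continuous and monotone in `U`
(patients whose last visit exceeds `U` contribute their last-visit age),
so bisection over the default bracket `[0, 120]` years always terminates;
the tolerance is 0.01 years.

The augmentation is a deliberate approximation: it asserts that no
censored patient outlives `U`, which the true process violates for its
longest-lived tail.  In parameter-recovery experiments this leaves a
visible signature — the middle-state sojourns are compressed by roughly
10-20% — while the first and last sojourns, the quantities that drive the
life-course and the cost model, are recovered well (see the test suite).
We consider this the right trade-off: the same device reduces the
final-state sojourn error from a factor of 3-10 to around 10%.

## Choosing the number of states

`select_num_states()` runs k-fold cross-validation (default five folds,
split by patient, never by visit) over candidate state counts (default
3-7, death included), fitting on the training folds and scoring the
held-out patients' log-likelihood.  Two methodological choices:

* **Selection sees observed events only** — visits, births and recorded
  deaths, not the censoring augmentation.  The augmented intervals are
  pseudo-data designed to repair rate bias; they are mis-specified by
  construction, and letting them drive model complexity rewards extra
  states for fitting an artefact.
* **Statistical ties resolve to parsimony.**  At realistic cohort sizes
  the held-out likelihood is nearly flat between the true state count and
  larger models (a few nats against fold standard deviations an order of
  magnitude larger).  The chosen count is therefore the smallest candidate
  whose deficit against the best mean is within one standard error of that
  deficit, computed from the *fold-paired* differences — the
  one-standard-error rule familiar from `glmnet` and `rpart`.  The raw
  argmax is always reported alongside.

## The cost model

Monthly societal costs attach to fitted states in four categories:

* **State benefits** — universal credit, employment support allowance and
  personal independence payment (PIP), with monthly amounts per
  state-keyed eligibility tier.  Defaults reproduce per-state means of
  12, 203, 1006 and 1586 GBP/month.
* **Therapies** — pharmacological and non-pharmacological prescriptions
  costed as unit cost x dosage x monthly frequency, with per-state default
  plans whose means are 22, 79, 158 and 271 GBP/month and a mean-one gamma
  dispersion across visits.
* **Lost GDP contribution** — a nominal disease-free salary is assigned by
  drawing a percentile and interpolating a salary quantile table; earnings
  halve at occupation status 2 and vanish at status 1, the loss being the
  gap to the nominal salary.  No loss accrues at or above the state
  pension age (66).  A death before pension age continues to incur the
  full nominal salary as lost GDP until pension age — an accounting
  convention that matters for intervention analysis, because delaying
  progression moves expensive years past retirement.
* **Care** — below a TFC of 9 the probability of needing daily care ramps
  from 1/3 (TFC 8) through 2/3 (TFC 7) to certainty (TFC 6 and below).
  Care-home residents incur the care-home cost (sticky once entered);
  otherwise a partnered patient's partner stops work with probability 1/2
  (costing the partner's forgone salary, drawn independently from the same
  salary table), else a care worker is hired, offset by local-authority
  funding net of PIP (never below zero).

Per-state total-cost distributions are fitted as a point mass at zero plus
a log-normal matched to the mean and variance of the positive totals.

## Intervention scenarios

`compare_scenarios()` simulates a synthetic population (default 10 000
patients) from the progression model and evaluates lifetime costs under a
baseline and under a hypothetical treatment that delays one transition by
`delay` years (entry into the target state and everything after it shifts
right).  Three couplings keep the comparison tight:

* one shared uniform variate per patient drives the cost quantile in
  *every* state (comonotone quantile coupling) — a patient is consistently
  cheap or expensive;
* each state's monthly total is split into the four categories by a
  Dirichlet draw (concentration 10, shares defaulting to the reference
  cost table's row proportions), drawn once and shared across arms;
* trajectories, salaries and all draws are common random numbers, so a
  zero-delay intervention yields exactly zero saving patient by patient.

With costs calibrated to the reference table and a 10-year delay of the
2 to 3 transition, the mean lifetime saving per patient is on the order of
GBP 100 000–160 000, and decomposition shows the saving comes entirely
from lost GDP (benefits, therapies and care all *increase* — the patient
lives longer in costly states), because lost GDP ends at retirement age
and the delay pushes expensive years past it.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of longitudinal HD
observational data: about 2.9 visits per patient (1 plus a negative
binomial, dispersion chosen to give a spread of about 1.9 visits),
roughly annual gaps (truncated normal, mean 1.1 y, floor 0.1 y), study
entry in mid-adulthood (normal, mean 48 y, sd 12 y), death recorded for
5% of patients, and raw scores drawn from per-state Gaussian profiles that
worsen monotonically — cognitive scores separate states 1/2 strongly while
TFC separates 2/3 — then clipped and rounded to each instrument's range.
Two design points deserve emphasis:

* **Enrolment by truncation.**  The entry age is drawn from the
  configured normal *truncated to the patient's living interval*;
  trajectories are never discarded.  Rejecting short-lived trajectories
  would tilt the cohort's latent law away from the generating model
  (survivors to age 48 die at 82 on average against the model's 65.3),
  which defeats the generator's purpose of producing exactly the
  statistical structure the analysis assumes.  The price is that a
  patient dying young is enrolled correspondingly early, which real
  cohorts achieve through juvenile-onset clinics.
* **Two kinds of emissions.**  When the generating model carries emission
  parameters (see `default_emission_model()`, whose PC1 trends upward
  while PC2 has a flat mean and growing variance, mirroring fitted HD
  models), the cohort also carries features drawn from those Gaussians.
  Parameter-recovery experiments use these correctly-specified features;
  the full PCA pipeline is exercised on the 12 raw scores, whose clipping
  and saturation make the features deliberately non-Gaussian — as in real
  instruments, where healthy patients pile up at the ceiling of TFC or the
  independence scale.

What passing tests do and do not show: recovery of the first and last
sojourn times within 15% under the documented censoring correction, a
five-state cross-validated optimum on most cohorts, and the qualitative
cost findings are demonstrated *under this generator*.  Real observational
registry data add missingness, visit-scheduling informativeness, covariate
drift and rater effects that the generator does not emulate.

## Numerical choices

* Transition probabilities use the distinct-rate hypoexponential closed
  form; rates closer than 2e-3 (relative) are nudged apart in the
  compiled path (the coefficients amplify round-off like 1/gap, and the
  nudge costs at most ~1e-4 in probability), while the R-level
  `transition_matrix()` falls back to `Matrix::expm()`.
* Optimisation is quasi-Newton BFGS on log rates, means and log standard
  deviations: first rates alone with emissions fixed, then jointly, then
  restart-polished until the log-likelihood gains less than 1e-3 nats;
  convergence tolerance 1e-7 (relative), at most 500 iterations per stage.
* Initialisation clusters visits on PC1 with k-means (fixed internal
  seed), orders clusters along the severity axis, and seeds rates from the
  clusters' mean ages with sojourns clamped to 2-40 years.
* Cross-validation fits use a lighter budget (60 iterations, tolerance
  1e-5, no restarts): model comparison needs relative, not absolute,
  optimisation depth, and all candidates share the budget.
* Degenerate inputs: zero-probability configurations return `-Inf` rather
  than erroring; states with fewer than 3 visits are skipped (with a
  warning) by the correlation check; groups too small for PCA are merged
  into a neighbour; a last visit at or beyond the calibrated bound yields
  a 0.01-year guard interval.
* Problem sizes: the shipped tests run cohorts of 60-2000 patients; the
  acceptance experiments use 2000 patients for recovery and selection,
  1000 per seed for the correction property, and 10 000 synthetic patients
  for the scenario, matching the published simulation scale.

## Known limitations

* The censoring augmentation compresses middle-state sojourns by 10-20% in
  recovery experiments; only the first and last states are recovered to
  within about 10%.  A per-patient or covariate-dependent bound might do
  better and is out of scope.
* Cross-validated selection at 2000 patients is a statistical coin-flip
  between 5 and 6 states roughly two cohorts in five even with the
  one-standard-error rule; the published analyses had an order of
  magnitude more patients.
* The cost model's eligibility tiers, therapy plans and care parameters
  are calibrated stand-ins for administrative data; they reproduce the
  reference per-state means but not their joint distribution.
* Everything is UK-specific (benefit structure, pension age 66, salary
  table) and ignores inflation, discounting, the intervention's own cost,
  and opportunity costs of family members other than a partner stopping
  work.
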