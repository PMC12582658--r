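---
title: "Methods: emulating a drug-initiation target trial with registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulating a drug-initiation target trial with registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ttemulate` estimates observational analogues of the intention-to-treat
and per-protocol effects of starting versus not starting an ACE
inhibitor/angiotensin receptor blocker after a myocardial infarction with
preserved ejection fraction, from linked registry-style tables. This
vignette documents the statistical model, the conventions the package
commits to where several defensible choices exist, what the synthetic
registry generator does and does not emulate, and the package's numerical
choices and limitations.

## The discrete-time hazard model

Follow-up is discretized into 30-day blocks ("months") numbered from 1,
sixty of them over the five-year horizon. The month is a deliberate
compromise: fine enough that the discrete-time hazard approximates a
continuous-time one at the event rates involved (well under 1% per
month), coarse enough that the person-month table stays tractable, and the
natural unit for spline knots placed at 6, 12, 24, and 48 months.

Each person contributes one row per month until their first event,
deviation (per-protocol only), or administrative end. The monthly hazard
follows a pooled logistic model

$$\operatorname{logit} h(t \mid A) = \beta_0 + \beta_A A + s(t) + A\,s(t),$$

where $A$ indicates the assigned strategy and $s(t)$ is a restricted cubic
spline. With four knots the basis is the linear term plus two nonlinear
terms

$$s_j(t) = \frac{(t-k_j)_+^3 - (t-k_3)_+^3\frac{k_4-k_j}{k_4-k_3}
  + (t-k_4)_+^3\frac{k_3-k_j}{k_4-k_3}}{(k_4-k_1)^2},$$

linear beyond the boundary knots. The $(k_4-k_1)^2$ divisor is a
normalization convention only; any full-rank variant of the basis yields
identical fitted hazards, so the choice matters for coefficient
reproducibility, not inference. The treatment-by-spline product terms let
the two arms have fully separate hazard shapes; the model's only real
restriction is smoothness of the log-hazard in time.

Cumulative incidence is the product-limit transform
$R_a(t) = 1 - \prod_{k \le t}(1 - h_a(k))$, and arms are contrasted by the
risk difference and risk ratio at each month (the ratio is reported only
once the reference risk is positive). A `"saturated"` time basis — one
hazard parameter per (arm, month) cell — is also available; its maximum
likelihood estimate has the closed form "weighted events over weighted
at-risk" per cell and is computed that way, which makes it exactly the
weighted discrete Kaplan–Meier estimator. The test suite asserts this
equivalence to $10^{-12}$.

## Adjustment

Confounding at baseline is handled by unstabilized inverse probability of
treatment weights: a logistic model of assignment on all baseline
covariates gives $\hat p_i$, and each person is weighted by
$1/\hat p_i$ (treated) or $1/(1-\hat p_i)$ (untreated). Because the
weighted pseudo-population is exchangeable over the measured covariates,
marginal risks are read directly off the weighted arm-by-time model with
no further standardization. In the `covariates_in_model` sensitivity mode
the covariates instead enter the outcome model, and risks must then be
standardized: every individual's covariate profile is pushed through the
fitted model under both counterfactual arms and the per-person cumulative
incidence curves are averaged over the cohort.

Numeric covariates enter the weight model linearly; any covariate with
missing values is first converted to categories that include an explicit
`"missing"` level (the missing-indicator approach), and categorical
covariates likewise carry a missing level. Raw values are always kept
alongside their categorized versions.

Estimated assignment probabilities at the numerical boundary (below
$10^{-10}$) are treated as positivity violations and reported as errors,
not silently inverted. Optional truncation caps the pooled weight
distribution at a percentile (99 in the protocol's sensitivity analysis);
by construction this alters at most 1% of weights.

## Per-protocol censoring and censoring weights

Dispensations are converted to coverage at a fixed one pill per day
(dosage is not observed in dispensation registers). Overlapping
dispensations stockpile: coverage extends from the later of the previous
coverage end + 1 and the dispense day, so no covered day is ever lost and
total coverage equals total pills dispensed. Treatment is continuous
while the gap between a coverage end and the next dispensation is
strictly less than the 90-day grace period (180 days and a fixed 90-day
supply per dispensation are available as sensitivity variants).

The deviation day in the treated arm is *coverage end + grace days* — the
first day on which non-adherence is established — rather than the
coverage end itself: within the grace window the person could still have
redeemed the strategy, so censoring earlier would discard
protocol-consistent person-time. A contraindication (hypotension, renal
artery stenosis; any diagnosis position, either care setting) on or
before that day makes stopping protocol-consistent and the person is
never censored. In the untreated arm the deviation day is the first
study-drug dispensation after time zero, unless preceded by a qualifying
indication (hypertension for the composite and heart-failure outcomes;
additionally heart failure for the death and infarction outcomes).
Continued treatment after a contraindication is treated as
protocol-consistent as well; the package takes the view that the strategy
constrains initiation/stopping, not behaviour after the strategy's own
escape clause has triggered.

Selection induced by censoring is adjusted with unstabilized inverse
probability of censoring weights: within each arm, a pooled logistic
model of remaining uncensored at month $t$ on baseline covariates,
time-varying covariates (new renal disease or diabetes diagnoses;
dispensations of beta-blockers and other concomitant classes) and the
same spline of time; the row weight is the running product of inverse
fitted probabilities and multiplies the baseline weight. The choice to
give the censoring model the same spline-in-time form as the outcome
model is a convention — the adherence model's true form is unknown — and
the month with every remaining row censored is reported as a positivity
failure.

Administrative censoring (end of study, or five years after baseline)
is assumed non-informative and receives no weights.

## Time zero and eligibility conventions

Time zero is set at *admission + 30 days* for both arms — a fixed landmark
at the end of the assignment window. A common landmark removes the
immortal person-time that arises if the treated arm's clock starts at its
(earlier, survival-conditioned) prescription date while the untreated
arm's starts later; its cost is that the first 30 days after admission
are outside follow-up for everyone. The alternative convention, time zero
at the assignment date for the treated arm, is exposed as
`time_zero_mode = "assignment"` but is not the default.

Eligibility criteria are applied in the order the protocol lists them, and
a person failing several criteria is counted only under the first — so
the flowchart always conserves counts (input = eligible + sum of
exclusions), while per-criterion counts are order-dependent; the final
eligible set is not, which the tests assert directly. Two boundary
conventions are worth stating. eGFR: eligible iff eGFR ≥ 15 (values below
the threshold are the contraindication). Prior drug use: the lookback for
previous ACEi/ARB dispensations ends the day *before* admission, because a
dispensation on the admission day itself is the treatment assignment, not
history; diagnosis lookbacks include the admission day. Missing values in
fields a criterion needs (age, LVEF, eGFR, occupational status) fail that
criterion, since eligibility cannot be confirmed from the registry record.

In the adherence engine, dispensations before the treated person's
assignment date are ignored (they affected eligibility, not adherence),
but the assignment dispensation itself — dated up to 30 days before the
landmark time zero — does contribute coverage into follow-up.

## The bootstrap

Confidence intervals are nonparametric bootstrap percentile intervals
(2.5th/97.5th of the replicate distribution), resampling *individuals*
with replacement and re-running the entire estimator — including
re-estimation of both weight models — inside every replicate; whether the
original analysis re-estimated weights per replicate is not recorded in
the protocol, and re-estimation is the statistically defensible default
because it propagates weight-estimation uncertainty. Failed replicates
(non-convergence) are excluded and counted; more than 10% failures aborts
the run. Fixed seeds reproduce intervals exactly. The protocol's 500
replicates are the default surface; the coverage simulation in the test
suite uses 200 replicates across 50 simulated cohorts of 500 individuals,
a size chosen so the whole suite runs in minutes while the binomial
error band around 95% coverage is still informative.

## The synthetic registry generator

The generator emits the five linked tables from a fully specified model:
baseline covariates with location/scale loosely matched to a
post-infarction population; assignment from a logistic model (its
coefficients are the confounding dial); a monthly outcome hazard with
covariate effects, a polynomial time trend, and a known treatment effect;
an adherence process (monthly stopping in the treated arm, crossover in
the untreated) realized as dispensation records at a 100-day supply — a
value chosen so the 90-day gap rule is exercised on both sides of the
boundary; post-baseline indication/contraindication diagnoses; and MCAR
missingness. Default stop/start rates (1.3%/0.39% monthly) leave roughly
46% of the treated and 79% of the untreated arm on protocol at five
years, matching the adherence levels reported for the registry population
this design emulates. Per-table random streams are laid out person-major,
so enlarging a cohort never perturbs existing individuals' draws — a
property the tests use, and one that makes regression hunting far easier.

`true_marginal_risk()` is the oracle: a fresh Monte Carlo draw of
covariates pushed through the closed-form hazard recursion under sustained
assignment, with its standard error reported. Tests compare it against
exact path enumeration on small configurations, and the estimation
pipeline against it on large ones.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real registries: informative (MNAR) missingness;
measurement error in diagnoses and LVEF; unmeasured confounding (the
weight models in the tests are correctly specified by construction, so
recovery results demonstrate the estimator, not robustness to
misspecification); dependence of adherence on post-baseline health shocks
beyond the optional covariate links; competing risks (death simply ends
follow-up for nonfatal outcomes); and realistic national code
dictionaries, which are reduced to small configurable prefix sets.

## Numerical choices

* Pooled logistic fits use iteratively reweighted least squares
  (quasi-binomial family, so non-integer weights are legitimate),
  convergence tolerance $10^{-10}$ on the deviance, at most 100
  iterations; collinear design columns are dropped and recorded in the
  fit's column ledger; suspected separation (|linear predictor| > 30 on a
  correctly-classified event row) flags the fit as non-converged.
* The saturated-basis MLE is computed in closed form (per-cell weighted
  event shares) rather than by IRLS, both for speed and because it makes
  the Kaplan–Meier equivalence exact rather than tolerance-limited.
* Standardized mean differences use the pooled-variance definitions
  $|p_1-p_2|/\sqrt{(p_1(1-p_1)+p_2(1-p_2))/2}$ and
  $|\bar x_1-\bar x_2|/\sqrt{(s_1^2+s_2^2)/2}$ (population variances;
  weighted variants substitute weighted moments). Multi-level categorical
  covariates report the maximum over level-wise binary SMDs — a declared
  convention, since no standard exists. Degenerate zero-variance
  comparisons return 0 when the proportions agree and a flagged infinity
  otherwise.
* Validation bands for stochastic recovery tests are three combined
  standard errors: the oracle's Monte Carlo error plus the estimator's
  sampling error approximated with Kish effective sample sizes from the
  final-month weights. The oracle error alone (at $2\times10^5$ draws) is
  an order of magnitude smaller than the estimator's sampling noise, so
  omitting the latter would make the band meaninglessly tight.
* Problem sizes in the test suite: recovery properties run at 20 000
  individuals over 60 months (about 1.1 million person-months), balance
  and flowchart properties at 3 000–6 000, bootstrap coverage at 50 × 500
  individuals × 200 replicates.

## Interfaces

All stages are plain functions over data frames, composable exactly as
the orchestrated `run_analysis()` composes them (the tests assert the two
routes agree bit-for-bit); configurations are R lists or YAML documents,
bundles round-trip through CSV (ISO-8601 dates, empty-field missing
sentinel) or Parquet. The package is an analysis library, so these
functions and configuration files *are* its operational interface; no
shell executable is shipped.

## Known limitations

Dose titration is invisible to the one-pill-per-day assumption; the
eligibility emulation cannot distinguish "no diagnosis" from "not
recorded"; per-protocol validity rests on censoring depending only on
measured covariates; and the risk-ratio bootstrap distribution can be
unstable in small subgroups when the reference risk is near zero (the
replicate-failure accounting surfaces this rather than hiding it).
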