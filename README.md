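# ttemulate

Target trial emulation for drug-initiation questions in linked registry
data, with inverse probability weighting and a fully known synthetic
data-generating process for validation.

## The scientific problem

Whether to start a renin–angiotensin blocker (ACE inhibitor or angiotensin
receptor blocker) after a myocardial infarction with *preserved* left
ventricular ejection fraction (LVEF ≥ 50%) cannot be answered from existing
randomized trials, and naive observational comparisons of users versus
non-users are distorted by confounding by indication and by misaligned
time zero. The target-trial-emulation framework addresses this by writing
down the protocol of the hypothetical pragmatic trial — eligibility,
treatment strategies, assignment, outcomes, follow-up, estimands — and
emulating each element in registry tables: hospital admissions, drug
dispensations, diagnoses, deaths, and outcome events.

`ttemulate` implements that pipeline end to end:

* **Cohort construction** — ordered eligibility screening (age 18–74,
  LVEF ≥ 50%, standard infarction care, no indication or contraindication
  for the drug class in a 3-year lookback, …) with a conserving exclusion
  flowchart; treatment assignment from a qualifying dispensation within 30
  days of admission; a common day-30 landmark time zero.
* **Adherence engine** — dispensations become continuous-coverage episodes
  at one pill per day; treatment is continuous while gaps between coverage
  end and the next dispensation stay under a 90-day grace period; the
  per-protocol deviation time is the first day non-adherence is
  established (coverage end + grace), or the first initiation in the
  untreated arm, with protocol-consistent stopping/initiation after
  contraindications/indications.
* **Estimation** — person-month expansion; discrete-time pooled logistic
  hazard model with an indicator of assigned strategy `A`, a restricted
  cubic spline in follow-up time `t` (knots at 6, 12, 24, 48 months), and
  their product:

  `logit h(t | A) = beta_0 + beta_A A + s(t) + A * s(t)`

  Cumulative incidence is `R_a(t) = 1 − prod_{k<=t} (1 − h_a(k))`, compared
  between arms as differences and ratios. Confounding is adjusted by
  **unstabilized inverse probability of treatment weights** `1/p̂(A = a | L)`
  from a logistic model on all baseline covariates; the per-protocol
  analysis censors at deviation and multiplies in **time-varying inverse
  probability of censoring weights** `prod_{k<=t} 1/P̂(uncensored at k | L,
  L_k, s(k))`. A weighted discrete Kaplan–Meier estimator is available as
  the nonparametric alternative.
* **Inference and diagnostics** — nonparametric bootstrap (resampling
  individuals, re-estimating all weights per replicate; 500 replicates in
  the protocol) with percentile confidence intervals; standardized mean
  differences before/after weighting; subgroup runs; CSV/JSON reports.
* **Synthetic registry generator** — emits all five linked tables from a
  configurable model (confounded assignment, monthly outcome hazards with
  a known treatment effect, stop/crossover adherence processes realized as
  dispensations, post-baseline indications/contraindications, MCAR
  missingness) plus Monte Carlo oracles (`true_marginal_risk()`) for the
  counterfactual risks, so every stage can be tested against ground truth.

## Worked example

A confounded synthetic registry with a modest protective effect
(log-odds ratio −0.15 on the monthly hazard):

```r
library(ttemulate)
report <- run_analysis(list(
  synthetic = list(n_individuals = 5000, seed = 2024,
                   treatment_coefs = c(age = 0.5, nstemi = -0.9, sbp = 0.5),
                   treatment_effect = -0.15),
  estimand = c("itt", "pp"), outcome = "composite",
  adjustment = "ipw", n_boot = 0, seed = 2024))
report
```

```
Effect estimates at horizon:
 subgroup estimand   outcome adjustment    n         R1         R0           RD
      all      itt composite        ipw 5000 0.04485893 0.05062280 -0.005763872
      all       pp composite        ipw 5000 0.03896214 0.05379253 -0.014830398
        RR
 0.8861408
 0.7243038
```

`R1`/`R0` are the 60-month cumulative incidences under the two strategies,
`RD`/`RR` their difference and ratio: assignment lowers 5-year risk by
about 0.6 percentage points, and sustained adherence by about 1.5 — the
per-protocol contrast is farther from the null than the intention-to-treat
analogue, as expected when adherence erodes over follow-up (49% of the
treated and 80% of the untreated arm are still on protocol at 60 months
here). The weights do their job on the three confounded covariates:

```r
report$balance
```

```
 covariate       type smd_unweighted smd_weighted
       age continuous          0.407        0.013
    nstemi     binary          0.398        0.007
       sbp continuous          0.446        0.016
```

Set `n_boot = 500` to add percentile confidence intervals to every
estimate (the full nonparametric bootstrap re-runs weight estimation in
each replicate, so expect it to dominate the runtime).

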