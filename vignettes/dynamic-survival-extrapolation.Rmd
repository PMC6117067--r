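---
title: "Dynamic survival modeling and long-horizon extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic survival modeling and long-horizon extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health-economic evaluation of oncology treatments needs time to progression
(TTP), time to treatment discontinuation (TTD) and time to death (TTDeath)
over patient lifetimes, while trials observe only one or two years of
follow-up. The traditional answer — fit a single parametric distribution to
each arm-level survival curve and extrapolate — struggles with
immunotherapies: a minority of patients achieve a durable objective
response and behave completely differently from nonresponders, hazards
decelerate after an early inflection, and a single distribution cannot
represent the resulting mixture. The mismatch barely affects medians
(which fall inside the observed window) but can change the extrapolated
*mean* survival, the quantity that drives cost-effectiveness, by a large
factor.

`dicesurv` implements both approaches side by side so they can be compared
under a controlled, fully synthetic truth:

* **Standard parametric analysis**: maximum-likelihood fits of six
  families (Weibull, exponential, log-normal, log-logistic, Gompertz,
  generalized gamma) to each arm-level endpoint, ranked by AIC/BIC with
  log-cumulative-hazard and quantile diagnostics, and extrapolated to the
  horizon.
* **Dynamic modeling**: a multivariate Cox regression on counting-process
  data in which objective response is a *time-dependent* state
  (nonresponse → response → post-response), baseline MSKCC risk enters as
  a fixed covariate, and the treatment effect is piecewise over an
  inflection point (3 months by default); its components are recombined
  into a patient-level microsimulation that projects all three endpoints
  over 25 years.

## The dynamic model

For endpoint $e \in \{\mathrm{TTP}, \mathrm{TTD}, \mathrm{TTDeath}\}$ the
hazard of patient $i$ at time $t$ (months since randomization) is

$$h_{ie}(t) = h_{0e}(t)\;
  \mathrm{HR}_e^{\mathrm{msk}(i)}\;
  \mathrm{HR}_e^{\mathrm{trt}(i,\,t)}\;
  \mathrm{HR}_e^{\mathrm{state}(i,\,t)},$$

where $h_{0e}$ is a Weibull baseline for the reference condition
(comparator arm, poor MSKCC risk, nonresponse), with the package-wide
convention $S(t) = \exp\{-(t/\lambda)^{\gamma}\}$, $\gamma$ = shape,
$\lambda$ = scale in months. The three multipliers are:

* `favorable` / `intermediate` versus poor MSKCC risk (constant);
* the treatment effect, piecewise over the inflection for progression and
  death (`treat_early` at or before 3 months, `treat_late` after) and a
  single constant `treat` for discontinuation;
* the response state: `response` after an objective response is achieved
  and `post_response` after a previously achieved response is lost
  (discontinuation and death only — see below).

Responder dynamics are governed by three further parameters: a per-arm
(optionally per-arm-by-risk-stratum) Bernoulli probability of being a
latent responder; a log-normal time from randomization to response; and a
Gompertz time from response to loss of response with hazard
$b\,e^{a d}$, $a \in \mathbb{R}$. A negative $a$ makes the distribution
improper: a fraction $\exp(b/a)$ of responders never lose response. That
durable-responder fraction is the mechanism behind the mean-versus-median
divergence the package is built to study.

Two structural rules connect the processes:

* **Response gating.** Response is a state achieved during follow-up: a
  latent responder whose sampled response time is not reached before
  progression or death never switches state. Realized response rates
  therefore sit slightly below the nominal probabilities; both are
  reported by the generator. Estimating response as if it were a baseline
  covariate instead produces the classical immortal-time bias, which the
  test suite demonstrates on generated data.
* **Loss of response manifests as progression.** Losing an objective
  response entails progressive disease, so a responder's progression time
  is the minimum of the sampled progression time and the loss time, and
  the progression model has no post-response state.

## Estimation

`build_counting_process()` splits each subject's observed follow-up into
`(start, stop]` episodes at the inflection point, the response time and
(for discontinuation and death) the loss time; covariates are constant
within episodes, exposure is conserved exactly, and the partial likelihood
is invariant to further over-splitting (a property test). `fit_cox()`
maximizes the counting-process partial likelihood via `survival::coxph()`
with Efron tie handling — continuous synthetic times make ties rare — and
reports Wald intervals.

One estimation subtlety follows from the loss-manifests-as-progression
rule: a progression event realized *by* loss of response is not a draw
from the progression hazard, so the progression counting process treats it
as end-of-risk (censoring at the loss time) rather than as an event.
Counting those deterministic events as hazard events would inflate the
response-state progression hazard ratio by the loss hazard (an upward
bias of order 50% under the default calibration) and make the generating
value unrecoverable. The loss process itself is estimated separately from
the responders' loss times.

The remaining components are estimated as:

* **Reference baselines**: Weibull fits (via `flexsurv`) restricted to
  comparator-arm, poor-risk patients who never achieved response, because
  the simulation multiplies this baseline by response-state hazard ratios,
  so it must represent nonresponse exposure. This conditioning induces a
  small selection effect (never-responders are slightly
  worse-than-average survivors within the stratum); at the default ~5%
  comparator response rate it is negligible.
* **Response submodels**: closed-form log-normal MLE on observed response
  times (responders only; the responder fraction is the observed per-arm
  response rate), and a Gompertz MLE on response-to-loss durations
  right-censored at the end of follow-up (`min(administrative cutoff,
  death)`), with negative shape permitted. With no observed losses the
  fit is degenerate and an improper near-flat fit is returned with a
  warning.
* **Inflection**: `assess_ph()` refits the piecewise model on a candidate
  grid (default 2, 3, 4, 6 months), reports per-candidate log-likelihoods
  and the Wald test of equal early/late effects plus a Schoenfeld global
  proportional-hazards test, and picks the likelihood-maximizing
  candidate — advisory, with 3 months the configuration default.

How the Cox hazard ratios and the parametric baseline are reconciled into
one hazard is genuinely open (a semiparametric Cox baseline could be
carried instead); this package multiplies the *refitted Weibull* baseline
by the Cox hazard ratios, which keeps the simulation fully parametric and
the generator/estimator loop closed.

## The microsimulation

`simulate_dynamic()` realizes each patient in continuous time: draw arm,
risk group and responder status, then the response and loss times, then
each endpoint by a single inversion of its piecewise integrated hazard,

$$t = H^{-1}(-\log u), \qquad
  H(t) = \sum_i m_i \left[ H_0(\min(t, s_{i+1})) - H_0(s_i) \right],$$

where the $m_i$ are the multiplier products over the episode grid. There
is no cycle discretization; the DICE framing (conditions updated at
events) survives in the schedule itself. If the total cumulative hazard
stays below $-\log u$ — e.g. a durable responder under a death hazard
ratio of 0.06 — the event time is infinite and the patient is truncated
at the horizon. `simulate_standard()` draws endpoint times independently
per arm from the fitted single distributions. `summarize_histories()`
reports medians, horizon-restricted means (the area under the simulated
Kaplan–Meier curve up to the horizon — means are *restricted at 300
months* and labeled as such) and landmark survival, with optional
patient-level bootstrap standard errors. Capping progression and
discontinuation at death (composite endpoints, trial-style reporting) is
the summary default and can be switched off to study the marginal laws.

## The synthetic trial generator

`generate_trial()` emulates a two-arm phase III structure: ~410/411
patients, three MSKCC strata, objective response rates near 25% versus
5%, administrative censoring at a 14-month minimum follow-up plus a
uniform 17-month accrual offset, and death truncating observed
progression and discontinuation (semi-competing; the endpoints truncate
nothing else). Each patient owns an RNG substream derived from
`(seed, id)`, so enlarging a cohort never reshuffles earlier patients.

A latent responder whose event precedes the sampled response time is
demoted; the demoted patient's endpoint times are re-inverted under the
nonresponse-only schedule *reusing the same uniform draw*. Because the
two schedules agree before the response time, this reproduces exactly the
conditional law of a subject whose covariate path never switches — the
generator is an exact time-varying-covariate Cox data-generating process,
which is what makes closed-loop recovery of the hazard-ratio table a fair
test of the estimation pipeline.

### Calibration defaults

Hazard ratios and response probabilities in the shipped default model
(`inst/extdata/default_model.json`) are the published multivariate trial
estimates. The underlying patient-level fits are not public, so the
remaining values are package **calibration** choices, fixed once:

| Parameter | Default | Rationale |
|---|---|---|
| TTDeath baseline | Weibull(1.1, 11.9) | reference median ≈ 8.5 mo, the published poor-risk comparator median |
| TTP baseline | Weibull(1.3, 6.0) | reference median ≈ 4.5 mo, near the published arm-level TTP medians |
| TTD baseline | Weibull(1.1, 5.0) | reference median ≈ 3.6 mo, near the published comparator TTD median |
| Time to response | log-normal(log 2.2, 0.45) | responses cluster around the first assessments; early enough that gating demotes only ~20% of latent responders |
| Time to loss | Gompertz(−0.04, 0.05) | ≈ 29% never-lose fraction, median ≈ 20 mo among losers: durable responses with a realistic loss fraction inside follow-up |
| MSKCC mix | 0.35 / 0.49 / 0.16 | a realistic second-line advanced-RCC trial mix (not printed in the source analysis) |
| Accrual | 17 mo uniform | a typical phase III accrual window consistent with a 14-month minimum follow-up |

What the generator does *not* emulate: the RECIST visit grid (response
and progression are observed in continuous time, not at scheduled scans),
informative dropout, treatment crossover, time-varying risk scores, and
background mortality. Passing tests therefore show that the estimation
and simulation machinery is correct *under the stated model*, not that
the model captures every feature of real trial data.

## Numerical choices

* Piecewise hazard inversion is analytic per piece (no root finding); the
  test suite checks it against adaptive quadrature + bisection to 1e-8 on
  a thousand random schedules.
* Parametric likelihoods are maximized by `flexsurv::flexsurvreg()`;
  non-convergence is flagged on the returned object, never silent.
  AIC-ranking uses BIC as tie-break and never discards families.
* Restricted means of fitted distributions use adaptive quadrature with
  absolute tolerance 1e-6 months; simulated restricted means integrate
  the Kaplan–Meier step function exactly.
* Monotone-likelihood Cox terms (no events in a covariate level) are
  flagged and reported with infinite confidence intervals; covariates
  without variation raise a collinearity error.
* Validation problem sizes were chosen to make Monte-Carlo error small
  relative to the tested tolerances: 20 replicate trials of 2,000
  patients per arm for hazard-ratio recovery, 50 replicates for
  inflection detection, 10,000 draws for distributional
  (Kolmogorov–Smirnov) checks.

## Known limitations

* The comparison of extrapolation approaches is internal to the synthetic
  world; no real patient-level data are shipped or fitted.
* The reference-baseline conditioning on never-responders is slightly
  informative, as discussed above.
* Summaries restrict means at the horizon; an extrapolated-beyond-horizon
  mean is deliberately not offered.
* The per-patient-substream RNG prioritizes reproducibility and cohort
  stability over raw speed; cohorts of ~10^5 patients simulate in
  seconds-to-minutes, not milliseconds.
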