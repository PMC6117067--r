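# dicesurv

Long-horizon survival extrapolation for two-arm oncology trials, comparing
the traditional approach — a single parametric distribution fitted per
arm-level endpoint — with **dynamic modeling**: a multivariate Cox
regression in which objective response is a time-dependent state and the
treatment effect is piecewise over an early inflection, recombined into a
patient-level DICE (discretely integrated condition event) microsimulation
over a 25-year horizon.

The package is aimed at biostatisticians and health-economic modelers who
need time to progression (TTP), time to treatment discontinuation (TTD)
and time to death (TTDeath) beyond trial follow-up, especially for
immunotherapies, where a durable-responder minority produces survival
plateaus that a single distribution cannot represent. Because real
patient-level immuno-oncology trial data are not public, the package
ships a synthetic trial generator with the same statistical structure, so
the whole pipeline is testable end to end and the estimation stage can be
validated by closed-loop parameter recovery.

## The model

For endpoint *e*, patient *i* has hazard

    h_ie(t) = h0_e(t) · HR_e[mskcc_i] · HR_e[treat_i(t)] · HR_e[state_i(t)]

with a Weibull reference baseline `S(t) = exp(-(t/λ)^γ)` (comparator arm,
poor MSKCC risk, nonresponse), a piecewise treatment effect (≤ 3 / > 3
months; single constant for discontinuation), and a response state
switching nonresponse → response → post-response at a log-normal response
time and a Gompertz loss-of-response time. A negative Gompertz shape `a`
is improper — a fraction `exp(b/a)` of responders never lose response —
and is the mechanism behind diverging extrapolated means. Loss of a
response manifests as progression, and response must be achieved while
progression- and death-free (otherwise: immortal-time bias, demonstrated
in the test suite). Estimation uses counting-process episode splitting
and `survival::coxph()`; parametric fits use `flexsurv`; simulation
realizes each endpoint by one analytic inversion of its piecewise
integrated hazard. See the vignette
(`vignettes/dynamic-survival-extrapolation.Rmd`) for the full account.

## Worked example

```r
library(dicesurv)

design <- trial_design(n_per_arm = c(treatment = 410, comparator = 411),
                       seed = 2025)
truth  <- default_dynamic_model()     # shipped calibration + published HRs
trial  <- generate_trial(design, truth)
attr(trial, "response_rates")
#>          arm nominal   realized   observed
#> 1 comparator    0.05 0.04136253 0.04136253
#> 2  treatment    0.25 0.16097561 0.16097561
```

Nominal versus realized responder fractions differ because response must
be achieved event-free (gating). Fit the dynamic model on the synthetic
trial and inspect the recovered death-endpoint hazard ratios:

```r
est <- fit_dynamic_model(trial, inflection = 3)
est$hr_fit$fits$death
#> Cox fit [death]: 821 subjects, 466 events, partial loglik -2820.59
#>           term     hr  lower upper       p
#>       response 0.0584 0.0187 0.182 9.9e-07
#>  post_response 0.6020 0.3190 1.140 1.2e-01
#>      favorable 0.2910 0.2240 0.379 4.1e-20
#>   intermediate 0.5330 0.4240 0.670 7.0e-08
#>    treat_early 0.5710 0.3440 0.951 3.1e-02
#>     treat_late 0.8730 0.7150 1.070 1.8e-01
```

The generating values (0.06, 0.49, 0.29, 0.61, 0.50, 0.94) sit inside
every interval. Extrapolate both ways over 25 years:

```r
os_w <- fit_parametric(endpoint_sample(trial[trial$arm == "treatment", ],
                                       "death"), "weibull")
extrapolate(os_w, horizon = 300)
#> Median: 20.02 months; RMST(300 mo): 26.21 months
#>   landmarks: s36 = 0.257, s60 = 0.086

cfg <- simulation_config(n_patients = 5000, seed = 99)
summ <- summarize_histories(simulate_dynamic(est$model, cfg), cfg)
subset(summ, endpoint == "death")
#>   endpoint        arm    n events median rmst   s36   s60
#> 5    death comparator 5000   4996   13.7 21.2 0.168 0.062
#> 6    death  treatment 5000   4980   17.8 28.6 0.247 0.111
```

The two approaches nearly agree on the treatment-arm median (20.0 vs 17.8
months) but not on the restricted mean (26.2 vs 28.6 months) or 5-year
survival (8.6% vs 11.1%): the dynamic model carries the durable-responder
plateau into the extrapolation, the single Weibull cannot. The gap widens
with the responder fraction — the pattern the method exists to expose.

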