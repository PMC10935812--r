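# linksurv

Survival analysis when event times come from **imperfect record linkage**:
a census cohort is probabilistically matched to death records, linkage fails
for part of the cohort, and a successful match may be wrong. `linksurv` is
for biostatisticians and epidemiologists analysing such linked historic
cohorts (and for methodologists evaluating estimators for them).

## The setting and the model

On the age-since-birth timescale, each census record carries a binary
exposure *X*, a covariate *Z*, the census age *W* (the one guaranteed
observation point: everyone was alive at the census), and an analysis age
*V = W + c*. A linked death record contributes a matched event age *T**
with a match score *p*<sub>match</sub> ∈ (0,1] — the probability the match
is true. An unmatched record is ambiguous: alive at *V*, or a linkage
failure.

Lifetimes are modelled by a Weibull accelerated failure-time (AFT) law

> log *T* = α₀ + α₁X + α₂Z + (1/p)ε,  ε ~ extreme value,

with survival S(t) = exp(−γtᵖ), γ = exp(−(α₀+α₁X+α₂Z))ᵖ, under which the
Cox log-hazard ratio for exposure is exactly β₁ = −α₁·p. The package
estimates β₁ (Cox), α₁ (AFT), and Kaplan–Meier median survival by exposure
group and covariate cell, under five missing-data strategies:

| tag | strategy |
|---|---|
| `cc` | complete case: unequivocal matches only |
| `ipw` | all matches, weighted by p<sub>match</sub> / fitted P(matched \| X, Z) |
| `cens` | nonmatches right-censored at the census age W |
| `mirm` | multiple imputation from a linear model for log min(T, τ) |
| `mics` | multiple imputation by inverting the Weibull conditional survival given survival to W |

Under `mirm`/`mics`, an equivocal match appears twice in each completed
dataset — its matched age with weight p<sub>match</sub>, an imputed age with
weight 1 − p<sub>match</sub> — and estimates are pooled across imputations
by Rubin's rules. See the vignette
(`vignettes/linked-survival-methods.Rmd`) for the mathematics and the
design choices.

## Worked example

```r
library(linksurv)
coh <- draw_cohort(scenario_preset(1), seed = 42)
coh
#> Linked cohort: 1000 records
#>   matched: 369 (36.9%), unequivocal scores > 0.8: 205
#>   census age w: 0.3-103.3 yrs; follow-up v - w: 50.0-50.0 yrs
#>   simulated truth present; event rate before v: 75.7%

fit <- linksurv(coh, "mics", seed = 1)
fit
#> linksurv fit: multiple imputation, conditional survival
#>   cohort n = 1000 ; B = 10 imputations
#>   beta1 (Cox log-HR)        1.341  (se 0.113)
#>   alpha1 (AFT log-ETR)     -0.228  (se 0.020)
#>   median X=1 / X=0 (yrs)    61.29 / 76.43
```

The cohort was generated with a true log-hazard ratio of 1.2
(α₁ = −0.2, p = 6). Only 37% of records were matched, yet
conditional-survival imputation recovers β₁ = 1.34 (se 0.11) and
α₁ = −0.23 — close to this cohort's fully-observed benchmark
(`linksurv(coh, "gold")` gives 1.30 and −0.22) — and group medians of 61.3
and 76.4 years against analytic values of 62.7 and 76.6. `coef(fit)`,
`summary(fit)` and `plot(fit)` expose the full estimate table and the
weighted KM curves.

Whole method-comparison studies run with
`run_study(scenario_preset(2), methods = c("cc","cens","mics"), K = 100)`,
which reports each method's bias against the same-replicate gold standard;
`run_sensitivity()` repeats the imputation arms under misspecified
imputation models. A thin command-line front-end with `simulate`,
`analyze` and `study` subcommands lives at `inst/cli/linksurv.R`.

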