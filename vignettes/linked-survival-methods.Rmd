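---
title: "Handling missing event times from imperfect record linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing event times from imperfect record linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linksurv)
```

## The problem

Historic census cohorts can be linked to death records to study mortality,
but without unique identifiers the linkage is probabilistic and incomplete.
On the age-since-birth timescale each subject carries a census age $W$
(everyone is observed alive once, at the census), an analysis age
$V = W + c$ for a calendar-constant follow-up $c$, and a latent lifetime
$T$. A linked vital record supplies a matched event age $T^\*$ together with
a match score $p_{match} \in (0, 1]$, the probability that the match is
true. Two features make this harder than ordinary censored data:

* An unmatched subject ($r = 0$) may be alive at $V$ **or** a linkage
  failure for someone who died. The census age is the only observation
  point, so right-censoring nonmatches at $W$ discards essentially all of
  their information and — worse — does so differentially if linkage success
  depends on covariates.
* A matched subject may be matched to the wrong record. Scores above a
  threshold $P$ (default 0.8) are treated as *unequivocal*; weaker
  (*equivocal*) matches carry both a possibly-wrong matched age and a
  residual probability $1 - p_{match}$ that the truth is something else.

Two working assumptions are made throughout: nobody alive at the analysis
date is matched to a death record, and each subject has at most one match
(the highest-scoring candidate).

## Models and estimands

Lifetimes follow a Weibull accelerated failure-time (AFT) model,

$$\log T = \alpha_0 + \alpha_1 X + \alpha_2 Z + \tfrac{1}{p}\,\varepsilon,
\qquad \varepsilon \sim \text{extreme value},$$

equivalently $S(t \mid X, Z) = \exp(-\gamma t^p)$ with
$\gamma = \exp(-(\alpha_0 + \alpha_1 X + \alpha_2 Z))^p$. Under this law the
AFT exposure coefficient and the Cox proportional-hazards log-hazard ratio
are linked exactly by $\beta_1 = -\alpha_1 p$ (`aft_to_cox()`). The
estimands are $\beta_1$, $\alpha_1$, the exposure-group Kaplan–Meier
medians $M_0, M_1$ (the smallest $t$ with $\hat S_{KM}(t) \le 0.5$; reported
as missing when the curve never reaches one half), the four
covariate-specific medians $M_{xz}$, and $M_1 - M_0$.

## The five missing-data strategies

`linksurv(cohort, method = ...)` runs one strategy end to end. The weighting
schemes are:

| method | unequivocal match | equivocal match | nonmatch |
|---|---|---|---|
| `cc` | 1 (event at $T^\*$) | 0 | 0 |
| `ipw` | $1/\hat\Pr(r{=}1\mid X,Z)$ | $p_{match}/\hat\Pr(r{=}1\mid X,Z)$ | 0 |
| `cens` | 1 | $p_{match}$ | 1, censored at $W$ |
| `mirm`/`mics` | 1 | $p_{match}$ at $T^\*$ **and** $1-p_{match}$ at $T^{imp}$ | 1 at $T^{imp}$ |

The IPW denominator is the *observed*-match propensity
$\hat\Pr(r = 1 \mid X, Z)$ from a maximum-likelihood logistic regression
(`fit_propensity()`); the propensity is always estimated, never taken from
the generative mechanism.

**Conditional-survival imputation (MICS).** A Weibull AFT working model is
fitted to the unequivocal matches (`fit_complete_case_aft()`). Because every
subject was alive at the census, missing event ages are drawn from the
distribution of $T$ *conditional on survival to* $W$:
$$F(t \mid W) = 1 - \exp\!\big(-\gamma\,(t^p - W^p)\big),$$
inverted in closed form at a Uniform(0,1) percentile $q$:
$$T^{imp} = \Big[W^p - \frac{\log(1 - q)}{\gamma}\Big]^{1/p} \ge W.$$
Draws beyond $V$ are stored as censored at $V$, mimicking the gold-standard
analysis. By default the imputation is *proper*: the working-model
parameters $(\alpha, \log\sigma)$ are redrawn from their asymptotic normal
distribution for each of the $B$ imputations, so Rubin's total variance is
valid; `proper = FALSE` gives the improper variant for ablation.

**Restricted-mean imputation (MIRM).** A linear model for
$E[\log\min(T, \tau)]$ on $(1, X, Z)$ is fitted to the unequivocal matches.
$\tau$ is a ceiling age beyond which lifetimes are not extrapolated.
Per imputation, coefficients are drawn from their sampling normal, log-times
from the residual normal around the predicted mean, and the exponentiated
draws are capped at $\tau$ and (by default) censored at $V$ when they exceed
it. Capping after exponentiation and censoring at $V$ are both configurable
because the procedure admits either reading; the defaults keep MIRM and MICS
comparable.

An equivocal match's observed $T^\*$ is *not* used to inform its imputation
draw: the imputed row represents the complement of the match, and the
conditional law conditions only on $(W, X, Z)$.

Estimates from the $B$ completed datasets are pooled with Rubin's rules
(`rubin_pool()`): total variance $\bar W + (1 + 1/B) B_{var}$. KM medians
have no closed-form model variance, so their pooled interval rests on the
between-imputation spread alone — an understatement of the total
uncertainty, flagged in the result object. $B = 10$ by default; the bias
summaries are insensitive to $B$ well below that.

## The synthetic-cohort generator

`draw_cohort(scenario_spec(...))` emulates the study conditions of the
evaluation design (`scenario_preset(1)` … `scenario_preset(5)`):

* $X, Z \sim$ Bernoulli(0.5) independently; $T$ Weibull with shape $p = 6$
  and AFT coefficients $\alpha = (4.4, -0.2, 0)$ (settings 1–2) or
  $(4.5, -0.2, -0.2)$ (settings 3–5), so $\beta_1 = 1.2$ throughout.
* $W \sim$ Uniform$(0, T)$ — the census falls at an arbitrary point of each
  life — and $V = W + 50$ years.
* Linkage: $\Pr(r = 1)$ is a link function of
  $\delta_0 + \delta_1 X + \delta_2 Z$, then forced to 0 for anyone alive at
  $V$. The design states a Binomial($\exp(\cdot)$) draw, but
  $\exp(-1 + 2) > 1$ for its own coefficient choices, so the default link is
  the inverse logit, which keeps every configuration a valid probability;
  an `exp` link is available and validity-checked at generation time.
* Match scores: Beta(8, 2), or Beta($8 - Z$, $2 + Z$) in setting 5 where
  linkage quality degrades with $Z = 1$. Scores above 0.8 reproduce the true
  event age exactly; weaker scores add Gaussian noise with SD
  $1.8^{1/p_{match}}$, so error grows steeply as the score drops.
* Noise can push a matched age below $W$ (logically impossible — the subject
  was alive at the census) or below zero; the default floors such draws at
  $W + 0.01$ years, with a raw mode for sensitivity work.

What the generator does **not** emulate: calendar-period trends in survival
or linkage quality, competing risks, missingness depending on unobserved
variables (MNAR), multiple candidate matches per record, and covariate
measurement error. Passing tests therefore demonstrate correctness of the
estimators under a clean MCAR/MAR linkage mechanism with a known parametric
lifetime law — not robustness to everything real archives do.

## The Monte Carlo study

`run_study()` draws `K` cohorts (replicate $k$ seeded `base_seed + k`, so
every method arm sees the same cohorts and bias contrasts are paired),
analyses each with the fully-observed gold standard (deaths before $V$
observed, survivors censored at $V$) plus each requested method, and
summarises mean bias against the same-replicate gold standard, the
empirical SE across replicates, and the mean model-based SE. Method arms
are re-seeded per replicate from the method's fixed index, so an arm's
results do not depend on which other arms run; failures are excluded and
counted, with a hard error past 20% for any method.
`run_sensitivity()` repeats the imputation arms with deliberately
misspecified imputation models (omitting $Z$; adding $X{\times}Z$) while
the analysis model stays $X + Z$.

The packaged checks run the design at its stated scale — 500 replicates of
$n = 1000$ for the gold-standard median summaries — and the method
comparison at 100 replicates per setting, enough to pin the direction and
ordering of the biases, which is what those checks assert.

```{r study, eval = FALSE}
st <- run_study(scenario_preset(2), methods = c("cc", "cens", "mics"),
                K = 100, base_seed = 1)
print(st)
plot(st)
```

## Numerical and design choices

* **Cox ties.** Weighted fits use the Breslow approximation. The package's
  central device is splitting one record into fractional-weight pseudo-rows,
  and the weighted Breslow partial likelihood is exactly invariant to such
  splitting; Efron's equal-share correction is not (a half-weight
  duplication shifts a 20-row fit by ~0.015). Simulated event times are
  continuous, so the approximations coincide there; real, coarsely rounded
  archives may tie, and a `ties` argument is exposed.
* **Variances with pseudo-rows.** Whenever any weight is fractional or a
  record contributes two rows, both `coxph` and `survreg` fits switch to a
  robust sandwich variance clustered on the record id.
* **Median boundary.** `km_median()` implements $\le 0.5$ with a $10^{-12}$
  guard so a curve hitting one half exactly (possible with unit weights and
  even row counts) returns that event time.
* **Propensity sanity.** `fit_propensity()` refuses cohorts with all-equal
  match indicators and errors on fitted probabilities within $10^{-10}$ of
  0 or 1 (separation) rather than producing unbounded weights; no weight
  truncation is applied by default.
* **Thresholds and presets.** $P = 0.8$ everywhere by default, matching the
  score law used in evaluation; analyses in which only perfect scores count
  as unequivocal are obtained by setting the threshold just below 1. MIRM
  presets pair $\tau = 80$ with $\tau = 120$ (near the median and the upper
  tail of generated lifetimes); 110 replaces 120 for application-style data
  capped near observed maxima.
* **Degenerate inputs.** Zero residual variance in the restricted-mean fit
  propagates as exactly reproducible imputations; `rubin_pool()` requires
  $B \ge 2$ and drops undefined per-imputation medians with a contributor
  count; `mics_invert()` rejects $q = 1$ (infinite lifetime).

## Known limitations

Match scores are taken at face value as true-match probabilities; no model
for score miscalibration is provided. The working models for both imputation
engines are parametric, and although the sensitivity harness quantifies
misspecification of the covariate structure, a non-Weibull lifetime law is
outside the family (no log-normal/log-logistic AFT). Medians pooled across
imputations carry between-imputation uncertainty only. The propensity model
is logistic in $(X, Z)$ with no interactions, mirroring the analysis model.
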