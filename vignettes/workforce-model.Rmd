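---
title: "A needs-based model of the global assistive technology workforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A needs-based model of the global assistive technology workforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atworkforce)
```

## The estimation problem

Access to assistive products (wheelchairs, hearing aids, prostheses,
communication devices, low-vision aids) requires a trained provision
workforce, and no global figure for the required size of that workforce was
available to planners. `atworkforce` implements a needs-based estimation
chain that answers the question: *if every country met its population's need
for assistive products at the service level of a high-access reference
country, how large would the provision workforce have to be?*

The chain has four stages, disaggregated throughout by five product domains
(cognition & communication, hearing, mobility & self-care, orthotics &
prosthetics, vision):

1. **Reference workforce.** Regional full-time-equivalent (FTE) tables from
   the reference country are pooled and scaled by the population ratio,
   $W_S = W_R \, P_S / P_R$, per domain and workforce class (clinical &
   non-clinical vs administrative). Densities are expressed as FTE per
   million population (FTEPM).
2. **Needs in surveyed countries.** Household-survey summaries give weighted
   counts of people needing products per domain. Counts are rounded and
   treated as binomial observations; the prevalence of need $p_N$ gets an
   exact (Clopper–Pearson) 95% interval and is multiplied by the country
   population. Adult-only surveys are adjusted with a child-prevalence
   factor $f$: $N = p_\text{adult}(P_{18+} + f\,P_{<18})$.
3. **Needs in unsurveyed countries.** A Bayesian linear mixed model on the
   fourth-root scale,
   $$p_N^{1/4} = \mu + a_d + \beta_{1,d}\,\text{medAge} + \beta_{2,d}\,\text{HDI} + \varepsilon,$$
   with domain-interacted fixed slopes and exchangeable domain intercepts
   $a_d \sim N(0, \sigma_a^2)$, is fit to the surveyed countries and
   predicts prevalence with 95% intervals for the rest. Summaries are
   verified nonnegative and back-transformed by the fourth power.
4. **Global scaling.** Per-country needs are aggregated to a global total
   $N_G$ per domain and the reference workforce is scaled by the need
   ratio, $W_G = W_S \, N_G / N_S$, with interval propagation, a prescriber
   head-count analogue, and a deterministic $\pm 50\%$ productivity
   sensitivity band.

## Model assumptions

The fourth-root transform is taken as given: across countries the raw
prevalence of need is strongly right-skewed, and the quarter power brings it
close to normal so that a Gaussian error model on the transformed scale is
defensible. The mixed model assumes linearity in median age and HDI within
each domain on that scale, exchangeable domain intercepts, and homoscedastic
residuals. The scaling stage assumes workforce size is proportional to the
number of people needing products at fixed productivity — the productivity
sensitivity band is the explicit acknowledgment that this constant differs
across health systems.

## Fitting: a blocked Gibbs sampler

The model is conjugate throughout, so `prevalence_lmm()` uses a blocked
Gibbs sampler written for this package:

* all 16 location parameters ($\mu$, five $a_d$, ten slopes) are drawn
  jointly from their multivariate-normal full conditional (one Cholesky
  solve per iteration), which eliminates the slow mixing a one-at-a-time
  updater would have on correlated coefficients;
* $\sigma_e$ and $\sigma_a$ carry half-Cauchy priors implemented by the
  inverse-gamma mixture (parameter-expansion) representation, so their full
  conditionals stay inverse-gamma.

Covariates are centered and scaled internally for sampler stability;
coefficients are mapped back to the natural covariate scale in all reported
summaries. The defaults are 2 chains of 13,000 iterations with 3,000
burn-in and thinning by 10 (2,000 retained draws), a $N(0, 10^2)$ prior on
standardized-scale coefficients, and half-Cauchy scale 1 on both standard
deviations — weakly informative, since the response lives in $[0,1]$.
Convergence is monitored by the split-chain potential scale reduction
factor (cutoff 1.05, warning above it) and effective sample sizes per
parameter. With only five domains $\sigma_a$ is weakly identified; its
prior scale is therefore an explicit argument (`scale_intercept`) rather
than a constant.

Two numerical choices matter in edge cases. The variance draws are floored
at $10^{-12}$ so that noise-free data (used by the equivalence checks) keep
the coefficient update well conditioned; and an (all but) exact preliminary
least-squares fit reports zero Cook's distances, since the raw ratios are
round-off noise in that case.

## Influence screening

Before fitting, a preliminary least-squares fit with the same fixed-effect
structure computes Cook's distance per observation; the most influential
observations are removed. The screening rule has two knobs: a distance
threshold and a cap on removals (default 2). For the threshold we use the
standard $4/n$ rule of thumb rather than an absolute cutoff such as 0.5: on
design sizes like this one (about 140 observations, 15 fixed-effect
columns) a planted gross outlier — residual ten times the noise standard
deviation — can have Cook's distance well below 0.5 at moderate leverage
(we observe values near 0.14) while clean observations stay below about
0.06, so an absolute 0.5 cutoff misses true gross outliers that $4/n$
separates cleanly. The cap keeps the screen from trimming more than the
intended worst few points when the $4/n$ line clips the bulk.

## Prediction

`predict.prevalence_lmm()` summarizes, per country-domain, the posterior
predictive distribution of the transformed prevalence by its median and
2.5/97.5 percentiles. With residual noise included (the default, since the
intervals feed per-country need CIs) the predictive distribution is a
normal mixture over the retained draws; its quantiles are computed by root
finding on the mixture CDF rather than by simulation, which makes
predictions deterministic and invariant to the order of input rows. A
`"mean"` mode summarizes only the regression surface. Negative summaries
are truncated to zero and counted (none occur on realistic covariates —
the count is reported so a user can see when extrapolation leaves the
supported region), then raised to the fourth power; because $y^4$ is
monotone on $[0,\infty)$, interval ordering survives back-transformation.

## Interval arithmetic in the scaling stage

Two conventions are deliberate and configurable:

* **Global aggregation** defaults to bound summation (sum of lower bounds,
  sum of upper bounds), which is conservative — it is never narrower than
  the Monte-Carlo alternative (`method = "monte-carlo"`) that samples each
  country's need from the normal distribution implied by its interval,
  truncated at zero.
* **Ratio propagation** uses opposite bounds:
  $W_{G,\text{low}} = W_S N_{G,\text{low}} / N_{S,\text{high}}$ and
  conversely. This is the widest interval consistent with the inputs, and
  it reproduces the published cognition & communication workforce interval
  exactly at its printed precision, which is why it is the default.

The deterministic sensitivity analysis multiplies the point estimates by
0.5 and 1.5 — a judgmental $\pm 50\%$ productivity variation, applied
element-wise so the all-domain band is the sum of the per-domain bands.

Shared administrative pools (two provision centers with common
administration) are allocated proportionally to the total workforce of the
pooled domains, rounded to whole FTE by largest remainder (ties broken by
position). That rule conserves the rounded pool exactly and keeps every
allocation within one FTE of its exact proportional share; the published
tables print integer allocations without stating a rule, and largest
remainder reproduces them.

Weighted survey counts are rounded half-to-even (base R `round`),
independently for the need count and the total; prevalence ties and CI
persons are kept at full precision internally and rounded only for display.

## The synthetic world

Because the underlying survey microdata are not public, the package ships a
generator whose defaults *are* the study conditions: 28 surveyed plus 161
unsurveyed countries, five domains, and prevalences generated from exactly
the structure the model assumes — fourth-root-scale linear predictors with
domain-specific median-age and HDI slopes, Gaussian noise (sd 0.02, which
places country prevalences in the realistic 0.5–10% range), and clamping of
the transformed value to $[0,1]$ before back-transformation. Covariates are
uniform on plausible ranges (median age 15–48 years, HDI 0.35–0.97,
populations log-uniform $10^5$–$1.4\times 10^9$), chosen to cover the
predictor space for recovery tests rather than to mimic the real joint
distribution. Surveys default to 9,000 respondents (the emulated
multi-country survey round averaged about 9,300 per country) with lognormal
design weights (log-sd 0.3) normalized in expectation, so weighted counts
are non-integer and exercise the rounding rule; the real survey's weighting
scheme is not public, so this weight model is a stand-in, not a
reconstruction. Child factors are drawn from $[0.2, 0.5]$, bracketing the
published judgmental values of 0.30 and 0.40. Regional workforce tables are
exact population-proportional shares of a national ground truth, so pooled
extrapolation recovers the truth to machine precision.

What passing tests on this world show — and do not show: parameter
recovery, interval calibration and round-trip conservation hold when the
generating process matches the model. They cannot detect misspecification
of the real data (non-Gaussian residuals, nonlinearity, informative survey
design, correlated domain needs within a country), and the survey CIs
ignore design effects, exactly as the estimation chain itself does.

## Worked example

The bundled reference inputs reproduce the published chain end to end:

```{r paper-mode}
res <- run_pipeline(list(mode = "direct-needs", seed = 1))
res
```

A fully synthetic run exercises every stage (shortened chains keep this
quick; defaults are 13,000 iterations):

```{r full-model}
res_syn <- run_pipeline(list(
  mode = "full-model", seed = 7,
  synthetic = list(n_surveyed = 12, n_unsurveyed = 15, survey_n = 3000),
  mcmc = list(n_iter = 2500, burn_in = 500, thin = 2)
))
res_syn$log[c("n_outliers_removed", "max_rhat", "n_truncated")]
```

## Problem sizes and limitations

The test suite runs the model at the study scale (28 × 5 observations,
161 × 5 predictions) with full-length chains for the recovery and coverage
checks, and shorter chains (2,000–4,000 iterations) for replicate-based
calibration checks, where 50 refits at full length would add nothing but
wall time; determinism, conservation and arithmetic checks run at toy
sizes.

Known limitations: the reference country's workforce reflects a
high-resource, specialist-heavy provision system, so the global figures
inherit that organizational model; the global CIs are conservative by
construction (bound summation plus opposite-bound ratios) and should be
read as outer bounds; the model predicts country prevalence from two
covariates only; and prescriber estimates are head counts, not FTE, because
prescribing is a part-time duty of a broad professional group.
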