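# atworkforce

Needs-based estimation of the global assistive technology provision
workforce.

More than 2.5 billion people need assistive products — wheelchairs, hearing
aids, prostheses, communication aids, low-vision devices — yet no global
estimate of the workforce required to provide them existed for planners.
`atworkforce` implements a transparent estimation chain for that number:
take a reference country with a high level of access to assistive products,
measure its provision workforce, estimate how many people need assistive
products there and everywhere else, and scale the reference workforce by
the need ratio. Everything is disaggregated by the five product domains of
assistive technology provision: cognition & communication, hearing,
mobility & self-care, orthotics & prosthetics, and vision.

The core quantities, in the field's notation:

- **Reference workforce**: regional workforce tables are pooled and scaled
  to the national population, `W_S = W_R · P_S / P_R`, separately for the
  clinical & non-clinical and the administrative workforce, with densities
  in FTE per million population (FTEPM).
- **Needs**: the prevalence of need `pN` in surveyed countries comes from
  weighted household-survey counts with exact binomial (Clopper–Pearson)
  95% CIs; unsurveyed countries get model-based predictions from a Bayesian
  linear mixed model on the fourth-root scale,
  `pN^(1/4) ~ medAge:domain + HDI:domain + (1|domain)`,
  fit by a blocked Gibbs sampler with an influence (Cook's distance) screen
  beforehand. Prevalences times populations give per-country needs `N`.
- **Global workforce**: `W_G = W_S · N_G / N_S` per domain, with
  opposite-bound interval propagation, prescriber head-count scaling, and a
  deterministic ±50% productivity sensitivity band
  (`W_G,low = 0.5 W_G`, `W_G,high = 1.5 W_G`).

A synthetic-world generator reproduces all inputs (country panel, weighted
surveys, regional workforce tables) from known ground truth, so the whole
chain is testable although the original survey microdata are not public.

## Worked example

The package bundles the published reference-country tables (Sweden, July
2023: combined workforce of three healthcare regions, national and global
need estimates). The default pipeline mode runs the arithmetic chain on
them:

```r
library(atworkforce)
res <- run_pipeline(list(mode = "direct-needs", seed = 1))
res
#> Assistive technology workforce pipeline run (mode: direct-needs, seed: 1)
#>
#> National workforce estimate (extrapolated from regional tables)
#>   national population: 10,551,707; regional population: 936,923 (8.9%)
#>                   domain total_fte clinical_fte total_ftepm clinical_ftepm
#>  cognition_communication     174.6        163.3        16.5           15.5
#>                  hearing    1185.9        929.1       112.4           88.1
#>        mobility_selfcare    2821.2       2100.4       267.4          199.1
#>    orthotics_prosthetics     773.7        627.3        73.3           59.4
#>                   vision     343.5        295.1        32.6           28.0
#>              all_domains    5298.8       4115.2       502.2          390.0
#>
#> Required global workforce (need-ratio scaling of the reference workforce)
#>   global population: 8,091,735,000
#>                   domain              total_mfte           clinical_mfte ftepm
#>  cognition_communication 0.0504 (0.0372; 0.0689) 0.0472 (0.0348; 0.0645)     6
#>                  hearing    0.383 (0.292; 0.507)      0.3 (0.228; 0.397)    47
#>        mobility_selfcare       2.28 (1.76; 2.98)        1.7 (1.31; 2.22)   281
#>    orthotics_prosthetics      1.13 (0.599; 2.16)     0.918 (0.486; 1.75)   140
#>                   vision     0.526 (0.248; 1.22)     0.451 (0.213; 1.04)    65
#>   all domains: 4.37 (2.93; 6.93) million FTE total; 3.41 (2.27; 5.47) clinical
#>   sensitivity (x0.5, x1.5): total 2.18-6.55, clinical 1.71-5.12 million FTE
#>
#> Prescribers (subset domains): 16.1 (12.2; 21.4) million
```

Reading the output: the three regions' 470.5 FTE scale to about 5,300 FTE
nationally (502 FTEPM); scaling each domain's workforce by the global-to-
reference need ratio implies a required global provision workforce of about
4.4 million FTE (3.4 million excluding administration), between 2.2 and 6.5
million under ±50% productivity, plus roughly 16 million prescribers in the
cognition/communication and mobility/self-care domains.

The statistical path — weighted surveys to prevalences, mixed-model fit,
prediction for unsurveyed countries, aggregation — runs on synthetic data
with known truth:

```r
res <- run_pipeline(list(mode = "full-model", seed = 42, synthetic = list()))
res$fit            # posterior summaries, convergence diagnostics
res$global_needs   # per-domain global needs with 95% bounds
```

Individual stages are exported (`extrapolate_national()`,
`survey_needs()`, `prevalence_lmm()` with `predict`/`coef`/`summary`
methods, `aggregate_global_needs()`, `required_workforce()`,
`sensitivity_bounds()`, `required_prescribers()`), as are the generators
(`generate_world()`, `make_fixtures()`). See the vignette
`vignettes/workforce-model.Rmd` for the model, priors, interval
conventions, and the generator's scope.

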