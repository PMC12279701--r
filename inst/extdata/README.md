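# Reference-country input tables

Published summary tables for the reference country (Sweden, July 2023) and
the corresponding global need estimates, used by the pipeline's "direct
needs" (paper) mode. All counts are persons unless noted.

- `sweden_regional_workforce.csv` — combined workforce of the three surveyed
  healthcare regions, one row per product domain: `region_id`, `population`
  (combined regional population), `domain`, `clinical_fte` (clinical and
  non-clinical provision workforce, full-time equivalents), `admin_fte`
  (administrative workforce; the one shared hearing/vision pool of 6 FTE is
  already resolved proportionally, 5 to hearing and 1 to vision).
- `sweden_needs.csv` — people needing assistive products in the reference
  country by domain with 95% confidence bounds: `domain`, `n_need`,
  `ci_low`, `ci_high`.
- `global_needs.csv` — global number of people needing assistive products by
  domain with 95% confidence bounds, same columns.
- `reference_config.json` — populations (national, under-18, 18-plus,
  combined regional, global), the national prescriber head count, the
  domains prescribers serve, and the reference-country child prevalence
  factor.

Synthetic fixtures written by `make_fixtures()` use these columns:
`country_panel.csv` (`country_id`, `population_total`,
`population_under18`, `population_18plus`, `median_age`, `hdi`,
`surveyed`), `survey_summaries.csv` (`country_id`, `domain`,
`weighted_need_count`, `weighted_total`, `adult_only`, `child_factor`),
`regional_workforce.csv` / `shared_admin_pools.csv` (as above, plus
`region_id`, `pool_fte`, `domains`), and `ground_truth.json` (true
coefficients, true national workforce, true global needs).
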