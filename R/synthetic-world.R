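## Synthetic world with known ground truth.
##
## Emulates the three pipeline inputs — a country covariate panel, weighted
## household-survey summaries for the surveyed countries, and regional
## workforce tables for a reference country — from the same generative
## structure the prevalence model assumes: fourth-root-scale linear
## predictors in median age and HDI with domain-specific coefficients and
## Gaussian noise.

## default generating coefficients on the transformed (fourth-root) scale,
## chosen so back-transformed prevalences fall in the realistic 0.5%-10% range
default_true_coefficients <- function() {
  doms <- at_domains()
  data.frame(
    domain = doms,
    intercept = c(0.10, 0.12, 0.15, 0.18, 0.08),
    slope_medage = c(0.004, 0.006, 0.007, 0.003, 0.005),
    slope_hdi = c(0.05, 0.02, 0.05, -0.05, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic world
#'
#' Bundles and validates the parameters of the synthetic-world generator.
#' Defaults mirror the study conditions the pipeline is designed for: 28
#' surveyed plus 161 unsurveyed countries, five product domains, residual
#' noise of 0.02 on the fourth-root scale, and per-country surveys of 9,000
#' respondents (the multi-country survey round this emulates averaged about
#' 9,300 respondents per country).
#'
#' @param n_surveyed,n_unsurveyed Counts of surveyed and unsurveyed
#'   countries.
#' @param true_coefficients Data frame with columns \code{domain},
#'   \code{intercept}, \code{slope_medage}, \code{slope_hdi} on the
#'   transformed scale.
#' @param residual_sd Noise sd on the transformed scale (> 0; may be set to 0
#'   for noise-free checks).
#' @param survey_n Respondents per survey.
#' @param weight_dispersion Log-scale sd of the lognormal design weights
#'   (0 gives equal weights).
#' @param child_factor_range Interval in \code{[0, 1]} from which per-country
#'   child prevalence factors are drawn.
#' @param seed Integer RNG seed; every downstream draw derives from it.
#'
#' @return A list of class \code{synthetic_world_config}.
#' @export
synthetic_world_config <- function(n_surveyed = 28, n_unsurveyed = 161,
                                   true_coefficients = default_true_coefficients(),
                                   residual_sd = 0.02, survey_n = 9000,
                                   weight_dispersion = 0.3,
                                   child_factor_range = c(0.2, 0.5),
                                   seed = 1) {
  check_scalar(n_surveyed, "n_surveyed", lower = 0, strict_lower = TRUE)
  check_scalar(n_unsurveyed, "n_unsurveyed", lower = 0, strict_lower = TRUE)
  check_scalar(residual_sd, "residual_sd", lower = 0)
  check_scalar(survey_n, "survey_n", lower = 0, strict_lower = TRUE)
  check_scalar(weight_dispersion, "weight_dispersion", lower = 0)
  if (length(child_factor_range) != 2 || any(child_factor_range < 0) ||
      any(child_factor_range > 1) ||
      child_factor_range[1] > child_factor_range[2])
    abort_at("`child_factor_range` must be an increasing interval within [0, 1]")
  check_columns(true_coefficients,
                c("domain", "intercept", "slope_medage", "slope_hdi"),
                "true_coefficients")
  check_scalar(seed, "seed")
  structure(list(n_surveyed = as.integer(n_surveyed),
                 n_unsurveyed = as.integer(n_unsurveyed),
                 true_coefficients = true_coefficients,
                 residual_sd = residual_sd,
                 survey_n = as.integer(survey_n),
                 weight_dispersion = weight_dispersion,
                 child_factor_range = child_factor_range,
                 seed = as.integer(seed)),
            class = "synthetic_world_config")
}

#' Generate the synthetic country panel with true prevalences
#'
#' Draws country covariates from plausible ranges (median age 15–48 years,
#' HDI 0.35–0.97, total population 1e5 to 1.4e9 on a log-uniform scale; the
#' under-18 population share decreases with median age) and computes the true
#' prevalence of each country-domain as the fourth power of the linear
#' predictor plus Gaussian noise, with the transformed value clamped to
#' \code{[0, 1]}. Deterministic given the config seed.
#'
#' @param config A \code{\link{synthetic_world_config}}.
#' @return A list of class \code{synthetic_world} with \code{countries} (the
#'   panel), \code{true_prevalence} (country x domain), \code{true_coefficients}
#'   and the config.
#' @export
generate_country_panel <- function(config) {
  if (!inherits(config, "synthetic_world_config"))
    abort_at("`config` must be a synthetic_world_config")
  set.seed(config$seed)
  n <- config$n_surveyed + config$n_unsurveyed
  id <- sprintf("C%03d", seq_len(n))
  median_age <- stats::runif(n, 15, 48)
  hdi <- stats::runif(n, 0.35, 0.97)
  pop <- round(exp(stats::runif(n, log(1e5), log(1.4e9))))
  ## younger populations have larger child shares; jitter keeps it non-exact
  child_share <- pmin(pmax(0.66 - 0.011 * median_age +
                             stats::rnorm(n, 0, 0.02), 0.10), 0.55)
  under18 <- round(pop * child_share)
  countries <- data.frame(
    country_id = id,
    population_total = pop,
    population_under18 = under18,
    population_18plus = pop - under18,
    median_age = median_age,
    hdi = hdi,
    surveyed = seq_len(n) <= config$n_surveyed,
    stringsAsFactors = FALSE
  )
  co <- config$true_coefficients
  prev <- do.call(rbind, lapply(seq_len(nrow(co)), function(j) {
    lin <- co$intercept[j] + co$slope_medage[j] * median_age +
      co$slope_hdi[j] * hdi +
      stats::rnorm(n, 0, config$residual_sd)
    y <- pmin(pmax(lin, 0), 1)
    data.frame(country_id = id, domain = co$domain[j],
               prevalence = inverse_transform_prevalence(y),
               stringsAsFactors = FALSE)
  }))
  structure(list(countries = countries, true_prevalence = prev,
                 true_coefficients = co, config = config),
            class = "synthetic_world")
}

#' Simulate a weighted household survey for one country
#'
#' Each respondent's need indicator per domain is Bernoulli in the true
#' prevalence; design weights are lognormal with the stated log-scale
#' dispersion, normalized by the lognormal mean so they average one in
#' expectation (with zero dispersion all weights are exactly one). Weighted
#' counts are returned unrounded, so they are generally non-integer and
#' exercise the downstream rounding rule.
#'
#' @param country_id Country label.
#' @param true_prevalence Named numeric vector of per-domain prevalences in
#'   \code{[0, 1]}.
#' @param survey_n Respondents (> 0).
#' @param weight_dispersion Nonnegative log-scale sd of the design weights.
#' @param seed Integer seed.
#' @param adult_only Was only the 18+ population sampled?
#' @param child_factor Child prevalence factor recorded with adult-only
#'   surveys.
#'
#' @return Data frame with one row per domain: \code{country_id},
#'   \code{domain}, \code{weighted_need_count}, \code{weighted_total},
#'   \code{adult_only}, \code{child_factor}.
#' @export
simulate_survey <- function(country_id, true_prevalence, survey_n,
                            weight_dispersion, seed,
                            adult_only = FALSE, child_factor = NA_real_) {
  check_scalar(survey_n, "survey_n", lower = 0, strict_lower = TRUE)
  check_scalar(weight_dispersion, "weight_dispersion", lower = 0)
  if (any(true_prevalence < 0 | true_prevalence > 1))
    abort_at("`true_prevalence` must lie in [0, 1]")
  set.seed(seed)
  ## one weight per respondent, shared across domains
  w <- stats::rlnorm(survey_n, 0, weight_dispersion) /
    exp(weight_dispersion^2 / 2)
  rows <- lapply(names(true_prevalence), function(d) {
    need <- stats::rbinom(survey_n, 1, true_prevalence[[d]])
    data.frame(country_id = country_id, domain = d,
               weighted_need_count = sum(w[need == 1]),
               weighted_total = sum(w),
               adult_only = adult_only, child_factor = child_factor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate regional workforce tables from a national ground truth
#'
#' Splits a stated fraction of the national population across regions and
#' assigns each region the exactly population-proportional share of the
#' national per-domain workforce, so that pooled extrapolation
#' (\code{\link{extrapolate_national}}) recovers the national truth to
#' machine precision. Optionally one region pools its administrative staff
#' for hearing and vision into a shared pool, exercising the
#' proportional-allocation step.
#'
#' @param national_truth Data frame with columns \code{domain},
#'   \code{clinical_fte}, \code{admin_fte}: the national ground truth.
#' @param national_population National population (persons).
#' @param n_regions Number of regions (>= 1).
#' @param covered_fraction Fraction of the national population covered by the
#'   regions (default 0.089, a realistic convenience sample of regions).
#' @param shared_admin Create a shared hearing+vision admin pool in the first
#'   region?
#' @param seed Integer seed (region population split).
#'
#' @return List with \code{regional} (region x domain table) and \code{pools}
#'   (shared-pool table, possibly empty).
#' @export
generate_regional_workforce <- function(national_truth, national_population,
                                        n_regions = 3,
                                        covered_fraction = 0.089,
                                        shared_admin = FALSE, seed = 1) {
  check_columns(national_truth, c("domain", "clinical_fte", "admin_fte"),
                "national_truth")
  check_scalar(n_regions, "n_regions", lower = 1)
  check_scalar(covered_fraction, "covered_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(national_population, "national_population", lower = 0,
               strict_lower = TRUE)
  set.seed(seed)
  shares <- stats::runif(n_regions, 0.5, 1.5)
  shares <- shares / sum(shares)
  region_pop <- national_population * covered_fraction * shares
  regional <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
    frac <- region_pop[r] / national_population
    data.frame(region_id = sprintf("R%02d", r),
               population = region_pop[r],
               domain = national_truth$domain,
               clinical_fte = national_truth$clinical_fte * frac,
               admin_fte = national_truth$admin_fte * frac,
               stringsAsFactors = FALSE)
  }))
  pools <- data.frame(region_id = character(0), pool_fte = numeric(0),
                      domains = character(0), stringsAsFactors = FALSE)
  if (shared_admin) {
    sel <- regional$region_id == "R01" &
      regional$domain %in% c("hearing", "vision")
    if (sum(sel) == 2) {
      pools <- data.frame(region_id = "R01",
                          pool_fte = sum(regional$admin_fte[sel]),
                          domains = "hearing;vision",
                          stringsAsFactors = FALSE)
      regional$admin_fte[sel] <- 0
    }
  }
  list(regional = regional, pools = pools)
}

#' Generate the complete synthetic world
#'
#' Chains the panel, survey and regional-workforce generators into one object
#' with every ground truth recorded: true coefficients, true prevalences,
#' true global needs (true prevalence times population, summed over
#' countries), and the true national workforce of the reference country (the
#' first surveyed country, given a workforce density profile comparable to a
#' high-access provision system). The reference-country survey is marked
#' adult-only with a child factor of 0.3, so the age-split adjustment is
#' exercised.
#'
#' @param config A \code{\link{synthetic_world_config}}.
#' @return A list of class \code{synthetic_world} with components
#'   \code{countries}, \code{true_prevalence}, \code{surveys},
#'   \code{regional}, \code{pools}, \code{true_national_workforce},
#'   \code{true_global_needs}, \code{reference_country},
#'   \code{true_coefficients}, \code{config}.
#' @export
generate_world <- function(config) {
  world <- generate_country_panel(config)
  countries <- world$countries
  prev <- world$true_prevalence

  surveyed <- countries$country_id[countries$surveyed]
  ref <- surveyed[1]
  set.seed(config$seed + 1L)
  child_factors <- stats::runif(length(surveyed), config$child_factor_range[1],
                                config$child_factor_range[2])
  surveys <- do.call(rbind, lapply(seq_along(surveyed), function(i) {
    cid <- surveyed[i]
    p <- prev$prevalence[prev$country_id == cid]
    names(p) <- prev$domain[prev$country_id == cid]
    adult_only <- cid == ref
    simulate_survey(cid, p, config$survey_n, config$weight_dispersion,
                    seed = config$seed + 100L + i,
                    adult_only = adult_only,
                    child_factor = if (adult_only) 0.3 else child_factors[i])
  }))

  ## reference-country workforce ground truth: density profile (FTEPM) of a
  ## high-access provision system, scaled to the reference population
  ref_pop <- countries$population_total[countries$country_id == ref]
  ftepm_total <- c(cognition_communication = 16.5, hearing = 112.3,
                   mobility_selfcare = 267.4, orthotics_prosthetics = 73.3,
                   vision = 32.5)
  clinical_frac <- c(cognition_communication = 0.935, hearing = 0.784,
                     mobility_selfcare = 0.744, orthotics_prosthetics = 0.811,
                     vision = 0.859)
  doms <- at_domains()
  total_fte <- ftepm_total[doms] * ref_pop / 1e6
  truth <- data.frame(domain = doms,
                      clinical_fte = as.numeric(total_fte * clinical_frac[doms]),
                      admin_fte = as.numeric(total_fte * (1 - clinical_frac[doms])),
                      stringsAsFactors = FALSE)
  reg <- generate_regional_workforce(truth, ref_pop, n_regions = 3,
                                     covered_fraction = 0.089,
                                     shared_admin = FALSE,
                                     seed = config$seed + 2L)

  pop <- countries$population_total[match(prev$country_id, countries$country_id)]
  needs <- prev$prevalence * pop
  true_global <- stats::aggregate(needs, by = list(domain = prev$domain), FUN = sum)
  names(true_global)[2] <- "n_need"

  world$surveys <- surveys
  world$regional <- reg$regional
  world$pools <- reg$pools
  world$true_national_workforce <- truth
  world$true_global_needs <- true_global
  world$reference_country <- ref
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d countries (%d surveyed), %d domains\n",
              nrow(x$countries), sum(x$countries$surveyed),
              length(unique(x$true_prevalence$domain))))
  if (!is.null(x$reference_country))
    cat(sprintf("  reference country: %s\n", x$reference_country))
  invisible(x)
}

#' Write synthetic-world fixtures to disk
#'
#' Writes the three input CSVs (country panel, survey summaries, regional
#' workforce plus shared pools) and a ground-truth JSON sidecar (true
#' coefficients, true national workforce, true global needs) for test
#' assertions. Byte-identical for identical config and seed.
#'
#' @param config A \code{\link{synthetic_world_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
make_fixtures <- function(config, dir) {
  world <- generate_world(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(countries = file.path(dir, "country_panel.csv"),
             surveys = file.path(dir, "survey_summaries.csv"),
             regional = file.path(dir, "regional_workforce.csv"),
             pools = file.path(dir, "shared_admin_pools.csv"),
             truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(world$countries, paths["countries"], row.names = FALSE)
  utils::write.csv(world$surveys, paths["surveys"], row.names = FALSE)
  utils::write.csv(world$regional, paths["regional"], row.names = FALSE)
  utils::write.csv(world$pools, paths["pools"], row.names = FALSE)
  truth <- list(true_coefficients = world$true_coefficients,
                true_national_workforce = world$true_national_workforce,
                true_global_needs = world$true_global_needs,
                reference_country = world$reference_country,
                residual_sd = config$residual_sd,
                seed = config$seed)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(paths)
}
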