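## Survey needs: weighted survey counts -> per-country needs with 95% CIs.

#' Prevalence of need with an exact binomial confidence interval
#'
#' Weighted survey counts are generally non-integer; they are rounded to the
#' nearest integer (round-half-to-even, applied to the need count and the
#' total independently) and treated as literal binomial counts. The 95%
#' interval is the exact Clopper–Pearson interval by default, which is
#' well defined at 0 and n and conservative; a Wald interval is available for
#' comparison.
#'
#' @param weighted_need_count Nonnegative weighted count of respondents
#'   needing the product (may be non-integer).
#' @param weighted_total Positive weighted total respondent count.
#' @param interval Interval type: \code{"clopper-pearson"} (exact, default)
#'   or \code{"wald"}.
#' @param level Confidence level (default 0.95).
#'
#' @return A list with \code{p_hat}, \code{ci_low}, \code{ci_high}, and the
#'   rounded counts \code{k} and \code{n}.
#' @export
#' @examples
#' prevalence_from_counts(52.4, 1000.2) # rounds to 52/1000
prevalence_from_counts <- function(weighted_need_count, weighted_total,
                                   interval = c("clopper-pearson", "wald"),
                                   level = 0.95) {
  interval <- match.arg(interval)
  check_scalar(weighted_need_count, "weighted_need_count", lower = 0)
  check_scalar(weighted_total, "weighted_total", lower = 0, strict_lower = TRUE)
  if (weighted_need_count > weighted_total)
    abort_at("weighted need count exceeds weighted total")
  k <- round(weighted_need_count)
  n <- round(weighted_total)
  if (n == 0) abort_at("weighted total rounds to zero observations")
  if (k > n) abort_at("need count exceeds total after rounding")
  p <- k / n
  if (interval == "clopper-pearson") {
    ci <- stats::binom.test(k, n, conf.level = level)$conf.int
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(max(0, p - half), min(1, p + half))
  }
  list(p_hat = p, ci_low = ci[1], ci_high = ci[2], k = k, n = n)
}

#' Persons needing assistive products from a prevalence estimate
#'
#' For a country surveyed across all ages, the number of people needing a
#' product is the prevalence times the total population; confidence bounds
#' scale identically.
#'
#' @param p_hat,ci_low,ci_high Prevalence point estimate and 95% bounds.
#' @param population Total population (persons).
#' @return A list with \code{n_need}, \code{ci_low}, \code{ci_high} (persons).
#' @export
needs_from_prevalence <- function(p_hat, ci_low, ci_high, population) {
  check_scalar(population, "population", lower = 0, strict_lower = TRUE)
  for (v in c(p_hat, ci_low, ci_high)) check_scalar(v, "prevalence", 0, 1)
  list(n_need = p_hat * population,
       ci_low = ci_low * population,
       ci_high = ci_high * population)
}

#' Needs adjustment for adult-only surveys
#'
#' Some surveys sample only respondents aged 18 and over. Child need
#' prevalence is then taken as a country-specific fraction of the adult
#' prevalence (reference-country default 0.30; 0.40 for younger populations),
#' so the need count is
#' \deqn{N = p_{adult} \cdot P_{18+} + f \cdot p_{adult} \cdot P_{<18},}
#' with confidence bounds mapped through the same linear transformation.
#'
#' @param p_hat,ci_low,ci_high Adult prevalence point estimate and 95% bounds.
#' @param population_18plus,population_under18 Age-split populations (persons).
#' @param child_factor Fraction in \code{[0, 1]} applied to the adult
#'   prevalence for the under-18 population.
#' @return A list with \code{n_need}, \code{ci_low}, \code{ci_high} (persons).
#' @export
#' @examples
#' adjust_adult_only(0.05, 0.04, 0.06, 8375483, 2176224, 0.30)
adjust_adult_only <- function(p_hat, ci_low, ci_high,
                              population_18plus, population_under18,
                              child_factor) {
  check_scalar(population_18plus, "population_18plus", lower = 0,
               strict_lower = TRUE)
  check_scalar(population_under18, "population_under18", lower = 0)
  check_scalar(child_factor, "child_factor", lower = 0, upper = 1)
  eff_pop <- population_18plus + child_factor * population_under18
  list(n_need = p_hat * eff_pop,
       ci_low = ci_low * eff_pop,
       ci_high = ci_high * eff_pop)
}

#' Per-country needs from survey summaries
#'
#' Converts weighted survey summaries into per-country, per-domain counts of
#' people needing assistive products with 95% confidence intervals. Surveys
#' flagged \code{adult_only} use the age-split adjustment of
#' \code{\link{adjust_adult_only}}; all others scale by the total population.
#'
#' @param surveys Data frame with columns \code{country_id}, \code{domain},
#'   \code{weighted_need_count}, \code{weighted_total}, \code{adult_only}
#'   (logical), \code{child_factor} (required where \code{adult_only}).
#' @param countries Data frame with columns \code{country_id},
#'   \code{population_total}, \code{population_under18},
#'   \code{population_18plus}.
#' @param interval,level Passed to \code{\link{prevalence_from_counts}}.
#'
#' @return Data frame with one row per country x domain: prevalence estimate
#'   (\code{p_hat}, \code{p_low}, \code{p_high}), need counts (\code{n_need},
#'   \code{ci_low}, \code{ci_high}), and \code{source = "surveyed"}.
#' @export
survey_needs <- function(surveys, countries,
                         interval = c("clopper-pearson", "wald"),
                         level = 0.95) {
  interval <- match.arg(interval)
  check_columns(surveys,
                c("country_id", "domain", "weighted_need_count",
                  "weighted_total", "adult_only"),
                "surveys")
  check_columns(countries,
                c("country_id", "population_total", "population_under18",
                  "population_18plus"),
                "countries")
  if (any(surveys$adult_only) && !"child_factor" %in% names(surveys))
    abort_at("`surveys` has adult-only rows but no `child_factor` column")

  rows <- lapply(seq_len(nrow(surveys)), function(i) {
    s <- surveys[i, ]
    ctry <- countries[countries$country_id == s$country_id, ]
    if (nrow(ctry) != 1L)
      abort_at(sprintf("country '%s' missing from the country panel", s$country_id))
    prev <- prevalence_from_counts(s$weighted_need_count, s$weighted_total,
                                   interval = interval, level = level)
    if (isTRUE(s$adult_only)) {
      if (is.na(ctry$population_18plus) || is.na(ctry$population_under18))
        abort_at(sprintf("country '%s' lacks the age split required by an adult-only survey",
                         s$country_id))
      if (is.na(s$child_factor))
        abort_at(sprintf("adult-only survey for '%s' lacks a child factor", s$country_id))
      nd <- adjust_adult_only(prev$p_hat, prev$ci_low, prev$ci_high,
                              ctry$population_18plus, ctry$population_under18,
                              s$child_factor)
    } else {
      if (is.na(ctry$population_total))
        abort_at(sprintf("country '%s' lacks a total population", s$country_id))
      nd <- needs_from_prevalence(prev$p_hat, prev$ci_low, prev$ci_high,
                                  ctry$population_total)
    }
    data.frame(country_id = s$country_id, domain = s$domain,
               p_hat = prev$p_hat, p_low = prev$ci_low, p_high = prev$ci_high,
               n_need = nd$n_need, ci_low = nd$ci_low, ci_high = nd$ci_high,
               source = "surveyed", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
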