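## Global scaling: aggregate country needs and scale the reference workforce
## by the global-to-reference need ratio, W_G = W_S * N_G / N_S.

#' Aggregate per-country needs to global totals
#'
#' Point estimates sum across countries per product domain. Interval bounds
#' are aggregated by bound summation by default (sum of lower bounds, sum of
#' upper bounds) — a conservative rule that never understates the interval. A
#' Monte-Carlo alternative samples each country's need independently from a
#' normal distribution implied by its interval (mean at the point estimate,
#' sd = interval width / 2*1.96, truncated at zero) and takes percentiles of
#' the summed replicates.
#'
#' @param country_needs Data frame with columns \code{country_id},
#'   \code{domain}, \code{n_need}, \code{ci_low}, \code{ci_high} and
#'   optionally \code{source}.
#' @param method \code{"bound-sum"} (default) or \code{"monte-carlo"}.
#' @param n_mc Monte-Carlo replicates (default 4000).
#' @param seed Seed for the Monte-Carlo method.
#' @param level Interval level assumed for the input CIs (default 0.95).
#'
#' @return Data frame with one row per domain: \code{domain}, \code{n_need},
#'   \code{ci_low}, \code{ci_high}; counts of surveyed/modeled countries as
#'   attributes.
#' @export
aggregate_global_needs <- function(country_needs,
                                   method = c("bound-sum", "monte-carlo"),
                                   n_mc = 4000, seed = 1, level = 0.95) {
  method <- match.arg(method)
  check_columns(country_needs,
                c("country_id", "domain", "n_need", "ci_low", "ci_high"),
                "country_needs")
  if (anyDuplicated(country_needs[, c("country_id", "domain")]))
    abort_at("duplicate country x domain rows in `country_needs`")
  tab <- table(country_needs$country_id)
  n_dom <- length(unique(country_needs$domain))
  if (any(tab != n_dom))
    abort_at("every country must have a row for every domain")

  doms <- unique(as.character(country_needs$domain))
  point <- tapply(country_needs$n_need, country_needs$domain, sum)[doms]
  if (method == "bound-sum") {
    lo <- tapply(country_needs$ci_low, country_needs$domain, sum)[doms]
    hi <- tapply(country_needs$ci_high, country_needs$domain, sum)[doms]
  } else {
    set.seed(seed)
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- hi <- stats::setNames(numeric(length(doms)), doms)
    for (d in doms) {
      rows <- country_needs[country_needs$domain == d, ]
      sds <- (rows$ci_high - rows$ci_low) / (2 * z)
      sims <- vapply(seq_len(nrow(rows)), function(i) {
        pmax(0, stats::rnorm(n_mc, rows$n_need[i], sds[i]))
      }, numeric(n_mc))
      tot <- rowSums(sims)
      qs <- stats::quantile(tot, c((1 - level) / 2, 1 - (1 - level) / 2),
                            names = FALSE)
      lo[d] <- qs[1]; hi[d] <- qs[2]
    }
  }
  src <- if ("source" %in% names(country_needs)) country_needs$source else "surveyed"
  per_country <- tapply(src, country_needs$country_id, function(s) s[1])
  structure(data.frame(domain = doms, n_need = as.numeric(point),
                       ci_low = as.numeric(lo), ci_high = as.numeric(hi),
                       stringsAsFactors = FALSE),
            n_countries_surveyed = sum(per_country == "surveyed"),
            n_countries_modeled = sum(per_country == "modeled"),
            method = method)
}

## internal: opposite-bound interval propagation for w * num/den
ratio_interval <- function(w, num, num_lo, num_hi, den, den_lo, den_hi) {
  w <- as.numeric(w); num <- as.numeric(num); den <- as.numeric(den)
  num_lo <- as.numeric(num_lo); num_hi <- as.numeric(num_hi)
  den_lo <- as.numeric(den_lo); den_hi <- as.numeric(den_hi)
  if (any(den <= 0)) abort_at("reference need must be positive (ratio undefined)")
  if (any(den_lo <= 0)) abort_at("reference need lower bound must be positive")
  list(point = w * num / den,
       lower = w * num_lo / den_hi,
       upper = w * num_hi / den_lo)
}

#' Required global workforce by need-ratio scaling
#'
#' Scales the reference country's per-domain workforce by the ratio of
#' global to reference need: \deqn{W_G = W_S \cdot N_G / N_S.}
#' Interval propagation uses opposite bounds — the lower bound divides the
#' numerator's lower bound by the denominator's upper bound, and vice versa —
#' which is the widest (most conservative) interval consistent with the input
#' intervals. Densities (FTEPM) are computed against the global population,
#' and productivity sensitivity bounds (\code{\link{sensitivity_bounds}})
#' multiply the point estimates by the given factors.
#'
#' @param w_ref Reference workforce: a \code{\link{extrapolate_national}}
#'   result or a data frame with columns \code{domain}, \code{total_fte},
#'   \code{clinical_fte}.
#' @param n_ref Reference-country needs: data frame with \code{domain},
#'   \code{n_need}, \code{ci_low}, \code{ci_high} (persons).
#' @param n_global Global needs in the same format.
#' @param global_population Global population (persons) for FTEPM.
#' @param sensitivity_factors Length-2 positive multipliers for the
#'   productivity sensitivity analysis (default \code{c(0.5, 1.5)}).
#'
#' @return An object of class \code{workforce_requirement}: one row per
#'   domain with point estimates, 95% intervals, FTEPM and sensitivity bounds
#'   for the total and the clinical & non-clinical workforce; all-domain
#'   totals available via \code{summary}.
#' @export
required_workforce <- function(w_ref, n_ref, n_global, global_population,
                               sensitivity_factors = c(0.5, 1.5)) {
  w_ref <- as.data.frame(w_ref)
  check_columns(w_ref, c("domain", "total_fte", "clinical_fte"), "w_ref")
  check_columns(n_ref, c("domain", "n_need", "ci_low", "ci_high"), "n_ref")
  check_columns(n_global, c("domain", "n_need", "ci_low", "ci_high"), "n_global")
  check_scalar(global_population, "global_population", lower = 0,
               strict_lower = TRUE)
  doms <- w_ref$domain
  if (!setequal(doms, n_ref$domain) || !setequal(doms, n_global$domain))
    abort_at("`w_ref`, `n_ref` and `n_global` must cover the same domains")
  nr <- n_ref[match(doms, n_ref$domain), ]
  ng <- n_global[match(doms, n_global$domain), ]
  if (any(nr$n_need <= 0)) abort_at("zero reference need: ratio undefined")

  tot <- ratio_interval(w_ref$total_fte, ng$n_need, ng$ci_low, ng$ci_high,
                        nr$n_need, nr$ci_low, nr$ci_high)
  cli <- ratio_interval(w_ref$clinical_fte, ng$n_need, ng$ci_low, ng$ci_high,
                        nr$n_need, nr$ci_low, nr$ci_high)
  out <- data.frame(domain = doms,
                    w_total = tot$point, w_total_low = tot$lower,
                    w_total_high = tot$upper,
                    w_clinical = cli$point, w_clinical_low = cli$lower,
                    w_clinical_high = cli$upper,
                    stringsAsFactors = FALSE)
  out$ftepm_total <- fte_per_million(out$w_total, global_population)
  out$ftepm_clinical <- fte_per_million(out$w_clinical, global_population)
  sens <- sensitivity_bounds(out, sensitivity_factors[1], sensitivity_factors[2])
  out <- cbind(out, sens[, -1])
  structure(out, class = c("workforce_requirement", "data.frame"),
            global_population = global_population,
            sensitivity_factors = sensitivity_factors)
}

#' Deterministic productivity sensitivity bounds
#'
#' Multiplies workforce point estimates by low/high productivity factors
#' (default 0.5 and 1.5, i.e. a 50% variation in workforce productivity).
#'
#' @param requirement Data frame with columns \code{domain}, \code{w_total},
#'   \code{w_clinical} (for example a \code{\link{required_workforce}}
#'   result).
#' @param low_factor,high_factor Positive multipliers (defaults 0.5, 1.5).
#' @return Data frame with per-domain sensitivity bounds for the total and
#'   clinical workforce.
#' @export
sensitivity_bounds <- function(requirement, low_factor = 0.5,
                               high_factor = 1.5) {
  check_scalar(low_factor, "low_factor", lower = 0, strict_lower = TRUE)
  check_scalar(high_factor, "high_factor", lower = 0, strict_lower = TRUE)
  req <- as.data.frame(requirement)
  check_columns(req, c("domain", "w_total", "w_clinical"), "requirement")
  data.frame(domain = req$domain,
             sens_total_low = req$w_total * low_factor,
             sens_total_high = req$w_total * high_factor,
             sens_clinical_low = req$w_clinical * low_factor,
             sens_clinical_high = req$w_clinical * high_factor,
             stringsAsFactors = FALSE)
}

#' @export
print.workforce_requirement <- function(x, ...) {
  cat("Required global workforce (need-ratio scaling of the reference workforce)\n")
  cat(sprintf("  global population: %s\n",
              format(attr(x, "global_population"), big.mark = ",")))
  df <- as.data.frame(x)
  show <- data.frame(domain = df$domain,
                     total_mfte = sprintf("%.3g (%.3g; %.3g)", df$w_total / 1e6,
                                          df$w_total_low / 1e6, df$w_total_high / 1e6),
                     clinical_mfte = sprintf("%.3g (%.3g; %.3g)", df$w_clinical / 1e6,
                                             df$w_clinical_low / 1e6,
                                             df$w_clinical_high / 1e6),
                     ftepm = round(df$ftepm_total))
  print(show, row.names = FALSE)
  s <- summary(x)
  cat(sprintf("  all domains: %.2f (%.2f; %.2f) million FTE total; %.2f (%.2f; %.2f) clinical\n",
              s$w_total / 1e6, s$w_total_low / 1e6, s$w_total_high / 1e6,
              s$w_clinical / 1e6, s$w_clinical_low / 1e6, s$w_clinical_high / 1e6))
  cat(sprintf("  sensitivity (x%.2g, x%.2g): total %.2f-%.2f, clinical %.2f-%.2f million FTE\n",
              attr(x, "sensitivity_factors")[1], attr(x, "sensitivity_factors")[2],
              s$sens_total_low / 1e6, s$sens_total_high / 1e6,
              s$sens_clinical_low / 1e6, s$sens_clinical_high / 1e6))
  invisible(x)
}

#' All-domain totals of a workforce requirement
#' @param object A \code{workforce_requirement}.
#' @param ... Unused.
#' @return Named list of all-domain sums (FTE) and densities.
#' @export
summary.workforce_requirement <- function(object, ...) {
  df <- as.data.frame(object)
  gp <- attr(object, "global_population")
  out <- as.list(colSums(df[, c("w_total", "w_total_low", "w_total_high",
                                "w_clinical", "w_clinical_low", "w_clinical_high",
                                "sens_total_low", "sens_total_high",
                                "sens_clinical_low", "sens_clinical_high")]))
  out$ftepm_total <- fte_per_million(out$w_total, gp)
  out$ftepm_clinical <- fte_per_million(out$w_clinical, gp)
  out$ftepm_total_low <- fte_per_million(out$w_total_low, gp)
  out$ftepm_total_high <- fte_per_million(out$w_total_high, gp)
  out$ftepm_clinical_low <- fte_per_million(out$w_clinical_low, gp)
  out$ftepm_clinical_high <- fte_per_million(out$w_clinical_high, gp)
  out
}

#' Required global prescribers by need-ratio scaling
#'
#' Scales the reference country's prescriber head count by the ratio of
#' global to reference need summed over the product domains prescribers
#' serve (cognition & communication plus mobility & self-care), with the
#' same opposite-bound interval propagation as
#' \code{\link{required_workforce}}.
#'
#' @param n_national National prescriber head count in the reference country.
#' @param ref_subset Reference-country needs for the subset: list or vector
#'   with \code{n_need}, \code{ci_low}, \code{ci_high} (persons).
#' @param global_subset Global needs for the subset in the same format.
#' @return List with \code{point}, \code{ci_low}, \code{ci_high} (persons).
#' @export
required_prescribers <- function(n_national, ref_subset, global_subset) {
  check_scalar(n_national, "n_national", lower = 0)
  ref_subset <- as.list(ref_subset)
  global_subset <- as.list(global_subset)
  for (nm in c("n_need", "ci_low", "ci_high")) {
    if (is.null(ref_subset[[nm]]) || is.null(global_subset[[nm]]))
      abort_at("subset needs require n_need, ci_low, ci_high")
  }
  if (ref_subset$n_need <= 0) abort_at("zero reference subset need: ratio undefined")
  r <- ratio_interval(n_national,
                      global_subset$n_need, global_subset$ci_low,
                      global_subset$ci_high,
                      ref_subset$n_need, ref_subset$ci_low, ref_subset$ci_high)
  list(point = r$point, ci_low = r$lower, ci_high = r$upper)
}
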