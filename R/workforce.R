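## Workforce extrapolation: regional FTE tables -> national estimates.
##
## A regional workforce table has one row per region x product domain:
##   region_id, population, domain, clinical_fte, admin_fte
## clinical_fte is the clinical and non-clinical (provision) workforce;
## admin_fte is the administrative workforce. Some regions pool
## administrative staff across two domains; such pools are given separately
## and resolved by proportional allocation before extrapolation.

#' Allocate a shared administrative pool across product domains
#'
#' Administrative staff shared between provision centers (for example a
#' hearing and a vision center with common administration) are split in
#' proportion to the total workforce of the pooled domains, with
#' largest-remainder rounding so the allocations are whole FTE summing to the
#' rounded pool size.
#'
#' @param pool_fte Nonnegative scalar; total FTE in the shared pool.
#' @param domain_weights Named nonnegative numeric vector; total workforce of
#'   each pooled domain, used as allocation weights. At least one weight must
#'   be positive when \code{pool_fte > 0}.
#'
#' @return Named integer vector of allocations summing to
#'   \code{round(pool_fte)}.
#' @export
#' @examples
#' allocate_shared_admin(6, c(hearing = 80, vision = 15)) # 5 and 1
allocate_shared_admin <- function(pool_fte, domain_weights) {
  check_scalar(pool_fte, "pool_fte", lower = 0)
  if (!is.numeric(domain_weights) || length(domain_weights) < 1L ||
      anyNA(domain_weights) || any(domain_weights < 0))
    abort_at("`domain_weights` must be a nonnegative numeric vector")
  total <- round(pool_fte)
  out <- integer(length(domain_weights))
  names(out) <- names(domain_weights)
  if (total == 0) return(out)
  if (sum(domain_weights) == 0)
    abort_at("all `domain_weights` are zero: no basis for allocating a positive pool")
  share <- total * domain_weights / sum(domain_weights)
  out[] <- as.integer(floor(share))
  left <- total - sum(out)
  if (left > 0) {
    rem <- share - floor(share)
    ## largest remainders get the leftover units; ties broken by position
    idx <- order(rem, decreasing = TRUE)[seq_len(left)]
    out[idx] <- out[idx] + 1L
  }
  out
}

## internal: fold shared admin pools into the per-domain admin column.
## `pools` has columns region_id, pool_fte, domains ("a;b" separated).
resolve_shared_admin <- function(regional, pools) {
  if (is.null(pools) || nrow(pools) == 0L) return(regional)
  check_columns(pools, c("region_id", "pool_fte", "domains"), "pools")
  for (i in seq_len(nrow(pools))) {
    doms <- strsplit(as.character(pools$domains[i]), ";", fixed = TRUE)[[1]]
    doms <- trimws(doms)
    sel <- regional$region_id == pools$region_id[i] & regional$domain %in% doms
    if (sum(sel) != length(doms))
      abort_at(sprintf("shared pool in region '%s' names domains absent from the table",
                       pools$region_id[i]))
    w <- regional$clinical_fte[sel] + regional$admin_fte[sel]
    names(w) <- regional$domain[sel]
    alloc <- allocate_shared_admin(pools$pool_fte[i], w)
    regional$admin_fte[sel] <- regional$admin_fte[sel] + alloc[regional$domain[sel]]
  }
  regional
}

#' FTE per million population
#'
#' Workforce density: full-time equivalents per million persons (FTEPM).
#'
#' @param fte Numeric vector of FTE counts.
#' @param population Population (persons); must be positive.
#' @return \code{fte * 1e6 / population}.
#' @export
#' @examples
#' fte_per_million(5297.8, 10551707) # ~502.1
fte_per_million <- function(fte, population) {
  check_scalar(population, "population", lower = 0, strict_lower = TRUE)
  if (!is.numeric(fte) || anyNA(fte)) abort_at("`fte` must be numeric")
  fte * 1e6 / population
}

#' Extrapolate a national workforce from regional tables
#'
#' Regions are pooled — FTE summed and populations summed — and the pooled
#' workforce is scaled by the ratio of the national population to the
#' combined regional population, per product domain and workforce class:
#' \deqn{W_S = W_R \cdot P_S / P_R.}
#' Densities (FTE per million population, FTEPM) are computed against the
#' national population.
#'
#' @param regional Data frame with columns \code{region_id},
#'   \code{population}, \code{domain}, \code{clinical_fte}, \code{admin_fte}
#'   (one row per region x domain).
#' @param national_population National population (persons); must be at least
#'   the combined regional population.
#' @param pools Optional data frame of shared administrative pools with
#'   columns \code{region_id}, \code{pool_fte}, \code{domains}
#'   (semicolon-separated domain names); resolved with
#'   \code{\link{allocate_shared_admin}} before pooling.
#'
#' @return An object of class \code{national_workforce}: a data frame with one
#'   row per domain and columns \code{domain}, \code{total_fte},
#'   \code{clinical_fte}, \code{total_ftepm}, \code{clinical_ftepm}, with the
#'   national and combined regional populations as attributes.
#' @export
#' @examples
#' reg <- data.frame(region_id = "r1", population = 936923,
#'                   domain = "cognition_communication",
#'                   clinical_fte = 14.5, admin_fte = 1.0)
#' extrapolate_national(reg, 10551707)
extrapolate_national <- function(regional, national_population, pools = NULL) {
  check_columns(regional,
                c("region_id", "population", "domain", "clinical_fte", "admin_fte"),
                "regional")
  if (any(regional$clinical_fte < 0) || any(regional$admin_fte < 0))
    abort_at("FTE values must be nonnegative")
  if (anyDuplicated(regional[, c("region_id", "domain")]))
    abort_at("a domain appears more than once within a region")
  regional <- resolve_shared_admin(regional, pools)

  pop_by_region <- tapply(regional$population, regional$region_id, function(p) p[1])
  p_r <- sum(pop_by_region)
  if (p_r <= 0) abort_at("combined regional population must be positive")
  check_scalar(national_population, "national_population",
               lower = p_r)

  ratio <- national_population / p_r
  doms <- unique(regional$domain)
  total <- tapply(regional$clinical_fte + regional$admin_fte, regional$domain, sum)
  clin  <- tapply(regional$clinical_fte, regional$domain, sum)
  out <- data.frame(
    domain        = doms,
    total_fte     = as.numeric(total[doms]) * ratio,
    clinical_fte  = as.numeric(clin[doms]) * ratio,
    stringsAsFactors = FALSE
  )
  out$total_ftepm    <- fte_per_million(out$total_fte, national_population)
  out$clinical_ftepm <- fte_per_million(out$clinical_fte, national_population)
  structure(out,
            class = c("national_workforce", "data.frame"),
            national_population = national_population,
            regional_population = p_r)
}

#' @export
print.national_workforce <- function(x, digits = 1, ...) {
  cat("National workforce estimate (extrapolated from regional tables)\n")
  cat(sprintf("  national population: %s; regional population: %s (%.1f%%)\n",
              format(attr(x, "national_population"), big.mark = ","),
              format(attr(x, "regional_population"), big.mark = ","),
              100 * attr(x, "regional_population") / attr(x, "national_population")))
  df <- as.data.frame(x)
  tot <- data.frame(domain = "all_domains",
                    total_fte = sum(df$total_fte),
                    clinical_fte = sum(df$clinical_fte),
                    total_ftepm = sum(df$total_ftepm),
                    clinical_ftepm = sum(df$clinical_ftepm))
  df <- rbind(df, tot)
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.national_workforce <- function(object, ...) {
  df <- as.data.frame(object)
  list(per_domain = df,
       all_domains = c(total_fte = sum(df$total_fte),
                       clinical_fte = sum(df$clinical_fte),
                       total_ftepm = sum(df$total_ftepm),
                       clinical_ftepm = sum(df$clinical_ftepm)),
       national_population = attr(object, "national_population"))
}

#' Extrapolate prescriber head counts by population ratio
#'
#' Prescribers are health professionals who prescribe assistive products as
#' part of broader duties, counted as persons (head counts), not FTE. The
#' national count is the source count scaled by the population ratio; reports
#' conventionally round it to the nearest thousand.
#'
#' @param n_prescribers Head count of prescribers in the source regions.
#' @param source_population Combined population of the source regions.
#' @param national_population National population.
#' @return National prescriber head count (unrounded).
#' @export
#' @examples
#' extrapolate_prescribers(1500, 565000, 10551707)
extrapolate_prescribers <- function(n_prescribers, source_population,
                                    national_population) {
  check_scalar(n_prescribers, "n_prescribers", lower = 0)
  check_scalar(source_population, "source_population", lower = 0,
               strict_lower = TRUE)
  check_scalar(national_population, "national_population", lower = 0,
               strict_lower = TRUE)
  n_prescribers * national_population / source_population
}
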