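## End-to-end pipeline: extrapolation -> needs -> model -> aggregation ->
## scaling, driven by a single configuration list with one root seed.

#' Load the bundled reference-country inputs
#'
#' Reads the published reference-country tables shipped with the package
#' (combined regional workforce, reference-country needs, global needs, and
#' populations; see \code{inst/extdata/README.md}).
#'
#' @return List with \code{regional}, \code{needs_reference},
#'   \code{needs_global} (data frames) and \code{params} (populations,
#'   prescriber count, child factor).
#' @export
reference_inputs <- function() {
  p <- function(f) system.file("extdata", f, package = "atworkforce",
                               mustWork = TRUE)
  list(regional = utils::read.csv(p("sweden_regional_workforce.csv")),
       needs_reference = utils::read.csv(p("sweden_needs.csv")),
       needs_global = utils::read.csv(p("global_needs.csv")),
       params = jsonlite::read_json(p("reference_config.json"),
                                    simplifyVector = TRUE))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file whose
#'   top level maps to the configuration list accepted by
#'   \code{\link{run_pipeline}}.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_at("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

## internal: run one stage with error context
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_at(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the workforce-estimation pipeline end to end
#'
#' Two entry modes:
#' \describe{
#'   \item{\code{mode = "direct-needs"}}{Needs are supplied directly (as
#'     published summary tables): regional workforce extrapolation, global
#'     scaling, sensitivity analysis and prescriber scaling run; the survey
#'     and model stages are bypassed. This is the default, using the bundled
#'     reference inputs.}
#'   \item{\code{mode = "full-model"}}{Surveys are converted to needs, the
#'     prevalence mixed model is fit to surveyed countries and predicts the
#'     unsurveyed ones, needs are aggregated globally, and the reference
#'     workforce is scaled. Inputs come either from a \code{synthetic} block
#'     (a \code{\link{synthetic_world_config}} or its argument list) or from
#'     an \code{inputs} list with \code{countries}, \code{surveys},
#'     \code{regional}, \code{pools}, \code{reference_country} and
#'     reference-workforce tables.}
#' }
#'
#' All randomness derives from \code{config$seed}, split deterministically
#' per stage; identical configuration and seed give identical results.
#'
#' @param config A configuration list (or a path readable by
#'   \code{\link{read_run_config}}). Recognized fields: \code{mode},
#'   \code{seed}, \code{synthetic}, \code{binomial_interval},
#'   \code{cooks_threshold}, \code{max_remove}, \code{mcmc} (list:
#'   \code{n_iter}, \code{burn_in}, \code{thin}, \code{chains}),
#'   \code{interval_type} (\code{"predictive"}/\code{"mean"}),
#'   \code{aggregation} (\code{"bound-sum"}/\code{"monte-carlo"}),
#'   \code{sensitivity_factors}.
#' @param quiet Suppress stage messages?
#'
#' @return An object of class \code{at_pipeline_result}: list with
#'   \code{national_workforce}, \code{country_needs}, \code{global_needs},
#'   \code{requirement}, \code{prescribers}, \code{log} (stage counts,
#'   outliers removed, truncations, convergence), and the resolved
#'   \code{config}.
#' @export
run_pipeline <- function(config = list(), quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  mode <- config$mode %||% "direct-needs"
  seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (!quiet) message(...)
  log <- list(mode = mode, seed = seed)

  sens <- config$sensitivity_factors %||% c(0.5, 1.5)

  if (mode == "direct-needs") {
    ref <- reference_inputs()
    regional <- config$regional %||% ref$regional
    needs_ref <- config$needs_reference %||% ref$needs_reference
    needs_glob <- config$needs_global %||% ref$needs_global
    params <- utils::modifyList(ref$params, config$params %||% list())

    say("stage: workforce extrapolation")
    natwf <- run_stage("workforce_extrapolation",
                       extrapolate_national(regional, params$national_population,
                                            pools = config$pools))
    say("stage: global scaling")
    req <- run_stage("global_scaling",
                     required_workforce(natwf, needs_ref, needs_glob,
                                        params$global_population,
                                        sensitivity_factors = sens))
    sub_doms <- params$prescriber_domains
    subs <- function(df) list(n_need = sum(df$n_need[df$domain %in% sub_doms]),
                              ci_low = sum(df$ci_low[df$domain %in% sub_doms]),
                              ci_high = sum(df$ci_high[df$domain %in% sub_doms]))
    presc <- run_stage("prescriber_scaling",
                       required_prescribers(params$prescribers_national,
                                            subs(needs_ref), subs(needs_glob)))
    log$n_countries_surveyed <- NA_integer_
    log$n_countries_modeled <- NA_integer_
    result <- list(national_workforce = natwf,
                   country_needs = NULL,
                   global_needs = needs_glob,
                   requirement = req, prescribers = presc,
                   fit = NULL, log = log, config = config)
    class(result) <- "at_pipeline_result"
    return(result)
  }

  if (mode != "full-model")
    abort_at("`mode` must be 'direct-needs' or 'full-model'")

  ## -- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    if (!inherits(syn, "synthetic_world_config"))
      syn <- do.call(synthetic_world_config,
                     utils::modifyList(as.list(syn), list(seed = seed)))
    say("stage: synthetic world generation")
    world <- run_stage("synthetic_world", generate_world(syn))
    countries <- world$countries
    surveys <- world$surveys
    regional <- world$regional
    pools <- world$pools
    ref_country <- world$reference_country
    ref_pop <- countries$population_total[countries$country_id == ref_country]
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    rd <- function(x) if (is.character(x)) utils::read.csv(x) else x
    countries <- rd(inp$countries); surveys <- rd(inp$surveys)
    regional <- rd(inp$regional)
    pools <- if (!is.null(inp$pools)) rd(inp$pools) else NULL
    ref_country <- inp$reference_country
    ref_pop <- countries$population_total[countries$country_id == ref_country]
    world <- NULL
  } else {
    abort_at("full-model mode needs a `synthetic` block or an `inputs` list")
  }

  ## -- reference workforce ------------------------------------------------
  say("stage: workforce extrapolation")
  natwf <- run_stage("workforce_extrapolation",
                     extrapolate_national(regional, ref_pop, pools = pools))

  ## -- surveyed-country needs ----------------------------------------------
  say("stage: survey needs")
  ivl <- config$binomial_interval %||% "clopper-pearson"
  sneeds <- run_stage("survey_needs",
                      survey_needs(surveys, countries, interval = ivl))
  log$n_surveyed_obs <- nrow(sneeds)

  ## -- prevalence model -----------------------------------------------------
  say("stage: prevalence model")
  mc <- config$mcmc %||% list()
  obs <- data.frame(country_id = sneeds$country_id, domain = sneeds$domain,
                    median_age = countries$median_age[
                      match(sneeds$country_id, countries$country_id)],
                    hdi = countries$hdi[
                      match(sneeds$country_id, countries$country_id)],
                    y = transform_prevalence(sneeds$p_hat))
  fit <- run_stage("prevalence_model", prevalence_lmm(
    obs,
    n_iter = mc$n_iter %||% 13000, burn_in = mc$burn_in %||% 3000,
    thin = mc$thin %||% 10, chains = mc$chains %||% 2,
    seed = seed + 1000L,
    cooks_threshold = config$cooks_threshold,
    max_remove = config$max_remove %||% 2,
    rhat_cutoff = config$rhat_cutoff %||% 1.05))
  log$n_outliers_removed <- nrow(fit$flagged)
  log$max_rhat <- fit$diagnostics$max_rhat
  log$converged <- fit$diagnostics$converged

  say("stage: prediction")
  unsurv <- countries[!countries$surveyed, ]
  grid <- merge(unsurv[, c("country_id", "median_age", "hdi",
                           "population_total")],
                data.frame(domain = fit$domains), by = NULL)
  pred <- run_stage("prediction",
                    predict(fit, grid,
                            interval = config$interval_type %||% "predictive"))
  log$n_truncated <- attr(pred, "n_truncated")
  log$n_countries_modeled <- nrow(unsurv)
  log$n_countries_surveyed <- sum(countries$surveyed)

  mneeds <- data.frame(country_id = pred$country_id, domain = pred$domain,
                       n_need = pred$p_hat * grid$population_total,
                       ci_low = pred$ci_low * grid$population_total,
                       ci_high = pred$ci_high * grid$population_total,
                       source = "modeled", stringsAsFactors = FALSE)
  country_needs <- rbind(sneeds[, names(mneeds)], mneeds)

  ## -- aggregation and scaling ---------------------------------------------
  say("stage: aggregation")
  gneeds <- run_stage("aggregation",
                      aggregate_global_needs(country_needs,
                                             method = config$aggregation %||% "bound-sum",
                                             seed = seed + 2000L))
  say("stage: global scaling")
  ref_needs <- sneeds[sneeds$country_id == ref_country,
                      c("domain", "n_need", "ci_low", "ci_high")]
  global_pop <- sum(countries$population_total)
  req <- run_stage("global_scaling",
                   required_workforce(natwf, ref_needs, gneeds, global_pop,
                                      sensitivity_factors = sens))

  presc <- NULL
  if (!is.null(config$prescribers_national)) {
    sub_doms <- config$prescriber_domains %||%
      c("cognition_communication", "mobility_selfcare")
    subs <- function(df) list(n_need = sum(df$n_need[df$domain %in% sub_doms]),
                              ci_low = sum(df$ci_low[df$domain %in% sub_doms]),
                              ci_high = sum(df$ci_high[df$domain %in% sub_doms]))
    presc <- run_stage("prescriber_scaling",
                       required_prescribers(config$prescribers_national,
                                            subs(ref_needs), subs(gneeds)))
  }

  result <- list(national_workforce = natwf, country_needs = country_needs,
                 global_needs = gneeds, requirement = req,
                 prescribers = presc, fit = fit,
                 world = if (!is.null(config$synthetic)) world else NULL,
                 log = log, config = config)
  class(result) <- "at_pipeline_result"
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.at_pipeline_result <- function(x, ...) {
  cat(sprintf("Assistive technology workforce pipeline run (mode: %s, seed: %d)\n\n",
              x$log$mode, x$log$seed))
  print(x$national_workforce)
  cat("\n")
  print(x$requirement)
  if (!is.null(x$prescribers))
    cat(sprintf("\nPrescribers (subset domains): %.1f (%.1f; %.1f) million\n",
                x$prescribers$point / 1e6, x$prescribers$ci_low / 1e6,
                x$prescribers$ci_high / 1e6))
  if (!is.null(x$fit))
    cat(sprintf("\nModel: %d outlier(s) removed, max Rhat %.3f, %d negative boundaries truncated\n",
                x$log$n_outliers_removed, x$log$max_rhat, x$log$n_truncated))
  invisible(x)
}

#' Serialize a pipeline result to machine-readable JSON
#'
#' Every number in a rendered report is traceable to a field of this JSON
#' document. Identical configuration and seed produce identical output.
#'
#' @param result An \code{\link{run_pipeline}} result.
#' @param path Output file; its directory must exist.
#' @return Invisibly, the path.
#' @export
write_results_json <- function(result, path) {
  if (!inherits(result, "at_pipeline_result"))
    abort_at("`result` must be an at_pipeline_result")
  s <- summary(result$requirement)
  nw <- summary(result$national_workforce)
  out <- list(
    log = result$log,
    national_workforce = list(per_domain = as.data.frame(result$national_workforce),
                              all_domains = as.list(nw$all_domains)),
    global_needs = as.data.frame(result$global_needs),
    workforce_requirement = list(per_domain = as.data.frame(result$requirement),
                                 all_domains = s),
    prescribers = result$prescribers
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
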