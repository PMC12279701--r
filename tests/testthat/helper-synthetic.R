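## model frame of surveyed-country true prevalences for fitting tests
surveyed_observations <- function(world) {
  ctr <- world$countries
  prev <- world$true_prevalence
  obs <- merge(prev[prev$country_id %in% ctr$country_id[ctr$surveyed], ],
               ctr[, c("country_id", "median_age", "hdi")],
               by = "country_id")
  obs$y <- transform_prevalence(obs$prevalence)
  obs
}

## short chains for tests that only need a valid posterior, not the default
## production length
fast_fit <- function(obs, seed, ...) {
  suppressWarnings(
    prevalence_lmm(obs, n_iter = 4000, burn_in = 1000, thin = 3,
                   seed = seed, ...)
  )
}
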