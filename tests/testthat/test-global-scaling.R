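make_needs <- function(ids, domains = c("hearing", "vision")) {
  df <- expand.grid(country_id = ids, domain = domains,
                    stringsAsFactors = FALSE)
  df$n_need <- 1000 * seq_len(nrow(df))
  df$ci_low <- df$n_need * 0.8
  df$ci_high <- df$n_need * 1.25
  df$source <- "surveyed"
  df
}

test_that("global aggregation sums points and bounds per domain", {
  one <- make_needs("A")
  g1 <- aggregate_global_needs(one)
  expect_equal(g1$n_need, one$n_need[match(g1$domain, one$domain)])
  expect_equal(g1$ci_low, one$ci_low[match(g1$domain, one$domain)])

  two <- make_needs(c("A", "B"))
  g2 <- aggregate_global_needs(two)
  for (d in unique(two$domain)) {
    rows <- two[two$domain == d, ]
    expect_equal(g2$n_need[g2$domain == d], sum(rows$n_need))
    ## bound summation: width is additive
    expect_equal(g2$ci_high[g2$domain == d] - g2$ci_low[g2$domain == d],
                 sum(rows$ci_high - rows$ci_low))
  }

  dup <- rbind(two, two[1, ])
  expect_error(aggregate_global_needs(dup), "duplicate")
  expect_error(aggregate_global_needs(two[-1, ]), "every domain")
})

test_that("bound-summation intervals are never narrower than Monte Carlo", {
  needs <- make_needs(sprintf("C%02d", 1:20))
  bs <- aggregate_global_needs(needs, method = "bound-sum")
  mc <- aggregate_global_needs(needs, method = "monte-carlo", seed = 4)
  expect_true(all(bs$ci_high - bs$ci_low >= mc$ci_high - mc$ci_low))
  ## both agree on the point estimate
  expect_equal(bs$n_need, mc$n_need)
})

test_that("aggregating true-prevalence needs recovers the generator truth", {
  world <- generate_world(synthetic_world_config(n_surveyed = 8,
                                                 n_unsurveyed = 12,
                                                 survey_n = 300, seed = 21))
  prev <- world$true_prevalence
  pop <- world$countries$population_total[
    match(prev$country_id, world$countries$country_id)]
  needs <- data.frame(country_id = prev$country_id, domain = prev$domain,
                      n_need = prev$prevalence * pop,
                      ci_low = prev$prevalence * pop,
                      ci_high = prev$prevalence * pop, source = "surveyed")
  agg <- aggregate_global_needs(needs)
  truth <- world$true_global_needs
  expect_equal(agg$n_need[match(truth$domain, agg$domain)], truth$n_need,
               tolerance = 1e-12)
})

test_that("workforce scaling follows W_G = W_S * N_G / N_S with opposite bounds", {
  w <- data.frame(domain = c("hearing", "vision"),
                  total_fte = c(1185.3, 343.2),
                  clinical_fte = c(929.1, 294.7))
  n_ref <- data.frame(domain = c("hearing", "vision"),
                      n_need = c(0.49e6, 0.05e6),
                      ci_low = c(0.39e6, 0.023e6),
                      ci_high = c(0.61e6, 0.099e6))
  n_glob <- data.frame(domain = c("hearing", "vision"),
                       n_need = c(158.3e6, 76.5e6),
                       ci_low = c(150.0e6, 71.6e6),
                       ci_high = c(166.6e6, 81.4e6))
  req <- required_workforce(w, n_ref, n_glob, 8.09e9)
  ## hand-ratio oracle for hearing: 1185.3 * 158.3/0.49 etc.
  h <- req[req$domain == "hearing", ]
  expect_equal(h$w_total, 1185.3 * 158.3 / 0.49, tolerance = 1e-12)
  expect_equal(h$w_total_low, 1185.3 * 150.0 / 0.61, tolerance = 1e-12)
  expect_equal(h$w_total_high, 1185.3 * 166.6 / 0.39, tolerance = 1e-12)
  expect_equal(round(h$w_total / 1e6, 2), 0.38)
  expect_equal(round(h$w_total_low / 1e6, 2), 0.29)
  expect_equal(round(h$w_total_high / 1e6, 2), 0.51)

  ## unit ratio: identical needs leave the workforce unchanged
  req_id <- required_workforce(w, n_ref, n_ref, 8.09e9)
  expect_equal(req_id$w_total, w$total_fte)

  ## linear in the global need
  n2 <- n_glob
  n2[, c("n_need", "ci_low", "ci_high")] <- n2[, c("n_need", "ci_low", "ci_high")] * 3
  req3 <- required_workforce(w, n_ref, n2, 8.09e9)
  expect_equal(req3$w_total, req$w_total * 3)

  ## opposite-bound intervals contain the point estimate
  expect_true(all(req$w_total_low <= req$w_total &
                    req$w_total <= req$w_total_high))

  ## all-domain totals are exact sums
  s <- summary(req)
  expect_equal(s$w_total, sum(req$w_total))
  expect_equal(s$w_clinical_low, sum(req$w_clinical_low))

  bad <- n_ref
  bad$n_need[1] <- 0
  expect_error(required_workforce(w, bad, n_glob, 8.09e9), "reference need")
})

test_that("sensitivity bounds are element-wise products of point estimates", {
  req <- data.frame(domain = c("a", "b"), w_total = c(100, 50),
                    w_clinical = c(80, 40))
  sb <- sensitivity_bounds(req)
  expect_equal(sb$sens_total_low, c(50, 25))
  expect_equal(sb$sens_total_high, c(150, 75))
  expect_equal(sb$sens_clinical_low, c(40, 20))
  id <- sensitivity_bounds(req, 1, 1)
  expect_equal(id$sens_total_low, req$w_total)
  expect_error(sensitivity_bounds(req, 0, 1.5), "low_factor")
})

test_that("prescriber scaling applies the subset need ratio", {
  ref <- list(n_need = 0.89e6, ci_low = 0.70e6, ci_high = 1.12e6)
  glob <- list(n_need = 511.0e6, ci_low = 488.3e6, ci_high = 533.8e6)
  pr <- required_prescribers(28000, ref, glob)
  expect_equal(pr$point, 28000 * 511.0e6 / 0.89e6, tolerance = 1e-12)
  expect_equal(pr$ci_low, 28000 * 488.3e6 / 1.12e6, tolerance = 1e-12)
  ## identity and linearity
  expect_equal(required_prescribers(28000, ref, ref)$point, 28000)
  expect_equal(required_prescribers(56000, ref, glob)$point, 2 * pr$point)
  expect_error(required_prescribers(28000, list(n_need = 0, ci_low = 0,
                                                ci_high = 1), glob),
               "reference subset")
})
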