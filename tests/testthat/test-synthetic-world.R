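test_that("noise-free prevalences equal the fourth power of the linear predictor", {
  cfg <- synthetic_world_config(residual_sd = 0, seed = 4)
  world <- generate_country_panel(cfg)
  co <- world$true_coefficients
  ctr <- world$countries
  for (j in seq_len(nrow(co))) {
    lin <- co$intercept[j] + co$slope_medage[j] * ctr$median_age +
      co$slope_hdi[j] * ctr$hdi
    lin <- pmin(pmax(lin, 0), 1)
    got <- world$true_prevalence$prevalence[
      world$true_prevalence$domain == co$domain[j]]
    expect_equal(got, lin^4, tolerance = 1e-12)
  }
})

test_that("panel generation is deterministic given the seed and covers valid ranges", {
  cfg <- synthetic_world_config(seed = 1)
  w1 <- generate_country_panel(cfg)
  w2 <- generate_country_panel(cfg)
  expect_identical(w1$countries, w2$countries)
  expect_identical(w1$true_prevalence, w2$true_prevalence)

  expect_equal(nrow(w1$countries), 189)
  expect_equal(nrow(w1$true_prevalence), 189 * 5)
  expect_true(all(w1$true_prevalence$prevalence >= 0 &
                    w1$true_prevalence$prevalence <= 1))
  expect_true(all(w1$countries$median_age >= 15 & w1$countries$median_age <= 48))
  expect_true(all(w1$countries$hdi >= 0.35 & w1$countries$hdi <= 0.97))
  expect_true(all(w1$countries$population_under18 +
                    w1$countries$population_18plus ==
                    w1$countries$population_total))
})

test_that("config validation names the offending field", {
  expect_error(synthetic_world_config(n_surveyed = 0), "n_surveyed")
  expect_error(synthetic_world_config(residual_sd = -1), "residual_sd")
  expect_error(synthetic_world_config(child_factor_range = c(0.5, 0.2)),
               "child_factor_range")
  expect_error(simulate_survey("X", c(d = 0.1), survey_n = 0,
                               weight_dispersion = 0, seed = 1),
               "survey_n")
})

test_that("survey simulation honors boundary prevalences and equal weights", {
  s0 <- simulate_survey("X", c(d1 = 0, d2 = 0.5), 500, 0.4, seed = 2)
  expect_equal(s0$weighted_need_count[s0$domain == "d1"], 0)

  ## zero dispersion: weights all one, weighted = unweighted counts
  s1 <- simulate_survey("X", c(d = 0.3), 500, 0, seed = 3)
  set.seed(3)
  invisible(stats::rlnorm(500, 0, 0))
  need <- stats::rbinom(500, 1, 0.3)
  expect_equal(s1$weighted_need_count, sum(need))
  expect_equal(s1$weighted_total, 500)

  ## with dispersion, weighted totals are non-integer (exercises rounding)
  s2 <- simulate_survey("X", c(d = 0.3), 500, 0.4, seed = 4)
  expect_false(s2$weighted_total == round(s2$weighted_total))
})

test_that("survey prevalence estimator is approximately unbiased", {
  est <- vapply(1:400, function(r) {
    s <- simulate_survey("X", c(d = 0.10), 1000, 0.3, seed = 10000 + r)
    s$weighted_need_count / s$weighted_total
  }, 0)
  expect_lt(abs(mean(est) - 0.10), 0.005)
})

test_that("regional tables round-trip through national extrapolation", {
  truth <- data.frame(domain = at_domains(),
                      clinical_fte = c(163.3, 929.1, 2100.4, 627.1, 294.7),
                      admin_fte = c(11.3, 256.2, 720.8, 146.4, 48.5))
  reg <- generate_regional_workforce(truth, 1e7, n_regions = 3,
                                     covered_fraction = 0.089, seed = 6)
  est <- extrapolate_national(reg$regional, 1e7, pools = reg$pools)
  expect_equal(est$total_fte[match(truth$domain, est$domain)],
               truth$clinical_fte + truth$admin_fte, tolerance = 1e-12)
  expect_equal(est$clinical_fte[match(truth$domain, est$domain)],
               truth$clinical_fte, tolerance = 1e-12)

  ## single region covering the full population reproduces the truth exactly
  reg1 <- generate_regional_workforce(truth, 1e7, n_regions = 1,
                                      covered_fraction = 1, seed = 6)
  est1 <- extrapolate_national(reg1$regional, 1e7)
  expect_equal(est1$total_fte[match(truth$domain, est1$domain)],
               truth$clinical_fte + truth$admin_fte, tolerance = 1e-12)

  ## shared admin: exactly one pool spanning hearing and vision
  regp <- generate_regional_workforce(truth, 1e7, shared_admin = TRUE, seed = 6)
  expect_equal(nrow(regp$pools), 1)
  expect_equal(regp$pools$domains, "hearing;vision")
  expect_error(generate_regional_workforce(truth, 1e7, n_regions = 0), "n_regions")
})

test_that("fixtures are byte-identical for identical config and seed", {
  cfg <- synthetic_world_config(n_surveyed = 6, n_unsurveyed = 8,
                                survey_n = 200, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixtures(cfg, d1)
  p2 <- make_fixtures(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = sprintf("fixture %s", nm))
  }
  panel <- utils::read.csv(p1[["countries"]])
  expect_equal(nrow(panel), 14)
  expect_equal(sum(panel$surveyed), 6)

  ## different seed: same schema, different surveys
  p3 <- make_fixtures(synthetic_world_config(n_surveyed = 6, n_unsurveyed = 8,
                                             survey_n = 200, seed = 6),
                      withr::local_tempdir())
  s1 <- utils::read.csv(p1[["surveys"]])
  s3 <- utils::read.csv(p3[["surveys"]])
  expect_identical(names(s1), names(s3))
  expect_false(identical(s1$weighted_need_count, s3$weighted_need_count))
})
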