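test_that("fourth-root transform and inverse are exact and round-trip", {
  expect_equal(transform_prevalence(0.0625), 0.5)
  expect_equal(transform_prevalence(c(0, 1)), c(0, 1))
  expect_equal(inverse_transform_prevalence(c(0, 1)), c(0, 1))
  p <- seq(0, 1, length.out = 101)
  expect_equal(inverse_transform_prevalence(transform_prevalence(p)), p,
               tolerance = 1e-12)
  expect_error(transform_prevalence(1.2), "\\[0, 1\\]")
  expect_error(transform_prevalence(-0.1), "\\[0, 1\\]")
  ## monotone back-transform preserves interval ordering
  y <- sort(stats::runif(50))
  expect_true(!is.unsorted(inverse_transform_prevalence(y)))
})

test_that("Cook's-distance screen matches a leave-one-out refit oracle", {
  set.seed(8)
  n <- 10
  df <- data.frame(country_id = rep(sprintf("c%02d", 1:n), 2),
                   domain = rep(c("hearing", "vision"), each = n),
                   median_age = rep(stats::runif(n, 15, 48), 2),
                   hdi = rep(stats::runif(n, 0.35, 0.97), 2))
  df$y <- 0.2 + 0.004 * df$median_age + 0.05 * df$hdi +
    (df$domain == "vision") * 0.05 + stats::rnorm(nrow(df), 0, 0.02)
  sc <- screen_outliers(df, threshold = Inf)
  X <- stats::model.matrix(~ 0 + domain + domain:median_age + domain:hdi,
                           data = transform(df, domain = factor(domain)))
  full <- stats::lm(df$y ~ 0 + X)
  p <- ncol(X)
  s2 <- sum(stats::residuals(full)^2) / (nrow(df) - p)
  oracle <- vapply(seq_len(nrow(df)), function(i) {
    loo <- stats::lm(df$y[-i] ~ 0 + X[-i, ])
    pred_loo <- as.numeric(X %*% stats::coef(loo))
    sum((stats::fitted(full) - pred_loo)^2) / (p * s2)
  }, 0)
  expect_equal(sc$cooks_distance, oracle, tolerance = 1e-8)
})

test_that("screen flags planted gross outliers and nothing on clean data", {
  cfg <- synthetic_world_config(seed = 9)
  obs <- surveyed_observations(generate_country_panel(cfg))
  set.seed(1)
  idx <- sample(nrow(obs), 2)
  obs$y[idx] <- obs$y[idx] + 10 * cfg$residual_sd
  sc <- screen_outliers(obs)
  expect_equal(sort(match(paste(sc$flagged$country_id, sc$flagged$domain),
                          paste(obs$country_id, obs$domain))),
               sort(idx))
  expect_equal(nrow(sc$kept), nrow(obs) - 2)
  expect_true(all(sc$flagged$cooks_distance > 4 / nrow(obs)))

  ## noise-free data has no influence outliers
  clean <- surveyed_observations(
    generate_country_panel(synthetic_world_config(residual_sd = 0, seed = 2)))
  expect_equal(nrow(screen_outliers(clean)$flagged), 0)

  ## infinite threshold disables the screen
  expect_identical(screen_outliers(obs, threshold = Inf)$kept, obs)

  ## collinear design is reported
  obs2 <- obs
  obs2$hdi <- obs2$median_age
  expect_error(screen_outliers(obs2), "collinear")
})

test_that("the sampler is deterministic given data and seed", {
  obs <- surveyed_observations(
    generate_country_panel(synthetic_world_config(n_surveyed = 10, seed = 3)))
  f1 <- fast_fit(obs, seed = 17)
  f2 <- fast_fit(obs, seed = 17)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$summary, f2$summary)
  f3 <- fast_fit(obs, seed = 18)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior means match OLS in the noise-free limit", {
  obs <- surveyed_observations(
    generate_country_panel(synthetic_world_config(residual_sd = 0, seed = 3)))
  fit <- fast_fit(obs, seed = 5)
  ols <- stats::lm(y ~ 0 + domain + domain:median_age + domain:hdi,
                   data = obs)
  co <- coef(fit)
  b <- stats::coef(ols)
  for (d in fit$domains) {
    expect_lt(abs(co[paste0("intercept_", d)] - b[paste0("domain", d)]), 1e-3)
    expect_lt(abs(co[paste0("slope_medage_", d)] -
                    b[paste0("domain", d, ":median_age")]), 1e-3)
    expect_lt(abs(co[paste0("slope_hdi_", d)] -
                    b[paste0("domain", d, ":hdi")]), 1e-3)
  }
})

test_that("prediction interpolates the data in the noise-free limit", {
  world <- generate_country_panel(synthetic_world_config(residual_sd = 0,
                                                         seed = 6))
  obs <- surveyed_observations(world)
  fit <- fast_fit(obs, seed = 7)
  new <- obs[c(3, 40, 77), c("country_id", "domain", "median_age", "hdi")]
  pred <- predict(fit, new, interval = "mean")
  expect_equal(pred$p_hat, obs$prevalence[c(3, 40, 77)], tolerance = 1e-2)
})

test_that("prediction is invariant to row order and intervals are ordered", {
  world <- generate_country_panel(synthetic_world_config(seed = 12))
  obs <- surveyed_observations(world)
  fit <- fast_fit(obs, seed = 13)
  uns <- world$countries[!world$countries$surveyed, ][1:8, ]
  grid <- merge(uns[, c("country_id", "median_age", "hdi")],
                data.frame(domain = fit$domains[1:2]), by = NULL)
  p1 <- predict(fit, grid)
  shuffle <- sample(nrow(grid))
  p2 <- predict(fit, grid[shuffle, ])
  expect_equal(p2[order(shuffle), c("p_hat", "ci_low", "ci_high")],
               p1[, c("p_hat", "ci_low", "ci_high")],
               ignore_attr = TRUE)
  expect_true(all(p1$ci_low <= p1$p_hat & p1$p_hat <= p1$ci_high))
  expect_true(all(p1$ci_low >= 0 & p1$ci_high <= 1))
  ## predictive intervals are at least as wide as mean-only intervals
  pm <- predict(fit, grid, interval = "mean")
  expect_true(all(p1$ci_high - p1$ci_low >= pm$ci_high - pm$ci_low - 1e-12))

  expect_error(predict(fit, transform(grid, median_age = NA)), "missing")
  expect_error(predict(fit, transform(grid, domain = "spectacles")), "unknown")
})

test_that("fit object methods are coherent", {
  obs <- surveyed_observations(
    generate_country_panel(synthetic_world_config(n_surveyed = 12, seed = 15)))
  fit <- fast_fit(obs, seed = 19)
  expect_s3_class(fit, "prevalence_lmm")
  expect_equal(fit$transform_exponent, 0.25)
  expect_gte(fit$n_draws, 1000)
  expect_length(residuals(fit), nrow(fit$data))
  expect_equal(fitted(fit) + residuals(fit), fit$data$y, tolerance = 1e-12)
  s <- summary(fit)
  expect_true(all(c("ess", "rhat") %in% names(s)))
  expect_true(all(s$q2.5 <= s$mean & s$mean <= s$q97.5))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(fit$data), 3L))
  expect_output(print(fit), "Gibbs")
  expect_error(prevalence_lmm(obs[obs$domain == "hearing", ]), "2 domains")
})
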