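## Bayesian linear mixed model for need prevalence.
##
## Model (on the fourth-root scale, y = pN^(1/4)):
##   y_i = mu + a_{d(i)} + b1_{d(i)} * medAge_i + b2_{d(i)} * HDI_i + e_i
##   a_d ~ N(0, sigma_a^2)   (exchangeable domain intercepts)
##   e_i ~ N(0, sigma_e^2)
## Fixed effects are domain-interacted slopes for median age and HDI.
## Priors: N(0, prior_sd^2) on mu and slopes (standardized-covariate scale);
## half-Cauchy on sigma_a and sigma_e via the inverse-gamma mixture
## (Huang & Wand parameter expansion), which keeps every full conditional
## conjugate, so the model is fit by a blocked Gibbs sampler.

#' Screen influential observations with Cook's distance
#'
#' A preliminary least-squares fit with the same fixed-effect structure as
#' the mixed model (domain intercepts plus domain-interacted median-age and
#' HDI slopes) computes Cook's distance per observation. Observations above
#' the threshold are flagged, and at most \code{max_remove} of them (the
#' largest distances) are removed before the MCMC fit.
#'
#' @param data Data frame with columns \code{domain}, \code{median_age},
#'   \code{hdi}, and the transformed response \code{y}.
#' @param threshold Cook's distance above which an observation is flagged.
#'   \code{NULL} (default) uses the standard \code{4/n} rule of thumb, which
#'   separates gross outliers cleanly at this design size; combined with
#'   \code{max_remove} it flags only the most influential points.
#' @param max_remove Maximum number of flagged observations to remove
#'   (largest distances first; default 2).
#'
#' @return A list with \code{kept} (data frame), \code{flagged} (data frame
#'   with a \code{cooks_distance} column), and \code{cooks_distance} (the full
#'   vector).
#' @export
screen_outliers <- function(data, threshold = NULL, max_remove = 2) {
  if (is.null(threshold)) threshold <- 4 / nrow(data)
  check_columns(data, c("domain", "median_age", "hdi", "y"), "data")
  check_scalar(max_remove, "max_remove", lower = 0)
  if (min(table(data$domain)) < 2)
    abort_at("each domain needs at least 2 observations for the screen")
  mf <- data.frame(domain = factor(data$domain),
                   median_age = data$median_age, hdi = data$hdi)
  X <- stats::model.matrix(~ 0 + domain + domain:median_age + domain:hdi,
                           data = mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort_at("singular preliminary design; collinear column(s): ",
             paste(bad, collapse = ", "))
  }
  fit <- stats::lm(data$y ~ 0 + X)
  d <- as.numeric(stats::cooks.distance(fit))
  d[!is.finite(d)] <- 0
  ## an (all but) exact fit has no influence outliers; the raw ratios are
  ## then pure round-off noise
  sig <- suppressWarnings(summary(fit)$sigma)  # warns on an exact fit
  if (sig < 1e-10 * max(1, stats::sd(data$y))) d[] <- 0
  over <- which(d > threshold)
  remove <- over[order(d[over], decreasing = TRUE)][seq_len(min(length(over), max_remove))]
  flagged <- data[remove, , drop = FALSE]
  if (length(remove)) flagged$cooks_distance <- d[remove]
  else flagged$cooks_distance <- numeric(0)
  kept <- if (length(remove)) data[-remove, , drop = FALSE] else data
  list(kept = kept, flagged = flagged, cooks_distance = d)
}

## internal: blocked Gibbs sampler for the conjugate Gaussian mixed model.
## C = [X | Z]; theta = (fixed coefficients, domain effects).
run_gibbs_chain <- function(C, y, n_fixed, n_rand, n_iter, burn_in, thin,
                            prior_sd, scale_e, scale_a, seed) {
  set.seed(seed)
  n <- length(y)
  p <- ncol(C)
  CtC <- crossprod(C)
  Cty <- crossprod(C, y)
  idx_rand <- seq.int(n_fixed + 1L, p)

  sig_e2 <- stats::var(y) / 2 + 1e-6
  sig_a2 <- 0.1^2
  xi_e <- xi_a <- 1
  theta <- rep(0, p)

  keep <- seq.int(burn_in + thin, n_iter, by = thin)
  draws <- matrix(NA_real_, length(keep), p + 2L,
                  dimnames = list(NULL, c(colnames(C), "sig_e2", "sig_a2")))
  k <- 0L
  for (it in seq_len(n_iter)) {
    prior_prec <- c(rep(1 / prior_sd^2, n_fixed), rep(1 / sig_a2, n_rand))
    P <- CtC / sig_e2
    diag(P) <- diag(P) + prior_prec
    R <- chol(P)
    m <- backsolve(R, forwardsolve(t(R), Cty / sig_e2))
    theta <- m + backsolve(R, stats::rnorm(p))

    resid <- y - as.numeric(C %*% theta)
    ## floor keeps the coefficient update well conditioned on noise-free data
    sig_e2 <- max(1 / stats::rgamma(1, shape = (n + 1) / 2,
                                    rate = 1 / xi_e + sum(resid^2) / 2), 1e-12)
    xi_e <- 1 / stats::rgamma(1, shape = 1, rate = 1 / scale_e^2 + 1 / sig_e2)

    a <- theta[idx_rand]
    sig_a2 <- max(1 / stats::rgamma(1, shape = (n_rand + 1) / 2,
                                    rate = 1 / xi_a + sum(a^2) / 2), 1e-12)
    xi_a <- 1 / stats::rgamma(1, shape = 1, rate = 1 / scale_a^2 + 1 / sig_a2)

    if (it %in% keep) {
      k <- k + 1L
      draws[k, ] <- c(theta, sig_e2, sig_a2)
    }
  }
  draws
}

## internal: split-chain potential scale reduction factor per column
split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    L <- floor(nrow(ch) / 2)
    halves <- c(halves, list(ch[seq_len(L), , drop = FALSE],
                             ch[seq.int(L + 1L, 2L * L), , drop = FALSE]))
  }
  L <- nrow(halves[[1]])
  m <- length(halves)
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    xs <- vapply(halves, function(h) mean(h[, j]), 0)
    ws <- vapply(halves, function(h) stats::var(h[, j]), 0)
    W <- mean(ws)
    B <- L * stats::var(xs)
    if (W <= 0) return(1)
    sqrt(((L - 1) / L * W + B / L) / W)
  }, 0)
}

#' Fit the fourth-root-scale prevalence mixed model by MCMC
#'
#' Fits a Bayesian linear mixed model of transformed need prevalence
#' \eqn{y = pN^{1/4}} on country median age and Human Development Index,
#' with domain-specific slopes (fixed effects) and exchangeable domain
#' intercepts (random effect with a shared variance). Sampling is by a
#' blocked Gibbs sampler: all regression coefficients and domain effects are
#' updated jointly from their multivariate-normal full conditional, and the
#' residual and intercept variances from conjugate inverse-gamma
#' conditionals under half-Cauchy priors (inverse-gamma mixture
#' parameterization). Covariates are centered and scaled internally;
#' coefficients are reported on the natural covariate scale.
#'
#' An optional preliminary Cook's-distance screen
#' (\code{\link{screen_outliers}}) removes grossly influential observations
#' before fitting.
#'
#' @param data Data frame with columns \code{country_id}, \code{domain},
#'   \code{median_age}, \code{hdi}, and either \code{prevalence} (natural
#'   scale, transformed internally) or \code{y} (already fourth-root scale).
#' @param n_iter Total MCMC iterations per chain (default 13000).
#' @param burn_in Burn-in iterations discarded per chain (default 3000).
#' @param thin Thinning interval (default 10; the defaults retain 1000 draws
#'   per chain).
#' @param chains Number of chains (default 2; needed for the split-chain
#'   convergence diagnostic).
#' @param seed Integer seed; chain c uses \code{seed + c - 1}.
#' @param prior_sd Standard deviation of the zero-mean Gaussian prior on the
#'   intercept and slopes, on the standardized-covariate scale (default 10,
#'   weakly informative).
#' @param scale_resid,scale_intercept Scales of the half-Cauchy priors on the
#'   residual and domain-intercept standard deviations (default 1; the
#'   response lives in [0, 1], so this is weakly informative).
#' @param screen Apply the Cook's-distance screen before fitting?
#' @param cooks_threshold,max_remove Passed to \code{\link{screen_outliers}}
#'   (\code{NULL} threshold uses the 4/n rule).
#' @param rhat_cutoff Convergence cutoff for the split-chain diagnostic; a
#'   warning is issued and recorded if any parameter exceeds it.
#'
#' @return An object of class \code{prevalence_lmm} with components including
#'   \code{summary} (posterior means, 95% credible intervals, effective
#'   sample sizes and split-chain diagnostics per parameter, on the natural
#'   covariate scale), \code{draws} (per-chain matrices), \code{flagged}
#'   (screened observations), and \code{diagnostics}.
#' @seealso \code{\link{predict.prevalence_lmm}}
#' @export
prevalence_lmm <- function(data, n_iter = 13000, burn_in = 3000, thin = 10,
                           chains = 2, seed = 1, prior_sd = 10,
                           scale_resid = 1, scale_intercept = 1,
                           screen = TRUE, cooks_threshold = NULL,
                           max_remove = 2, rhat_cutoff = 1.05) {
  cl <- match.call()
  check_columns(data, c("country_id", "domain", "median_age", "hdi"), "data")
  if (!"y" %in% names(data)) {
    check_columns(data, "prevalence", "data")
    data$y <- transform_prevalence(data$prevalence)
  }
  if (length(unique(data$domain)) < 2)
    abort_at("observations must span at least 2 domains")
  check_scalar(n_iter, "n_iter", lower = 1)
  if (burn_in >= n_iter) abort_at("`n_iter` must exceed `burn_in`")
  n_draws <- chains * floor((n_iter - burn_in) / thin)
  if (n_draws < 1000)
    warning("fewer than 1000 retained draws; increase n_iter or reduce thin")

  flagged <- data[0, , drop = FALSE]
  flagged$cooks_distance <- numeric(0)
  if (screen) {
    sc <- screen_outliers(data, threshold = cooks_threshold,
                          max_remove = max_remove)
    data <- sc$kept
    flagged <- sc$flagged
  }

  domains <- sort(unique(as.character(data$domain)))
  dfac <- factor(data$domain, levels = domains)
  center <- c(median_age = mean(data$median_age), hdi = mean(data$hdi))
  scale_ <- c(median_age = stats::sd(data$median_age), hdi = stats::sd(data$hdi))
  if (any(scale_ == 0)) abort_at("a covariate is constant; cannot standardize")
  ma <- (data$median_age - center[1]) / scale_[1]
  hd <- (data$hdi - center[2]) / scale_[2]

  D <- stats::model.matrix(~ 0 + dfac)             # domain indicators (random)
  colnames(D) <- paste0("a_", domains)
  X <- cbind("(mu)" = 1, D * ma, D * hd)
  colnames(X) <- c("(mu)", paste0("b_medage_", domains), paste0("b_hdi_", domains))
  C <- cbind(X, D)
  n_fixed <- ncol(X)
  n_rand <- ncol(D)

  draws <- lapply(seq_len(chains), function(ch) {
    run_gibbs_chain(C, data$y, n_fixed, n_rand, n_iter, burn_in, thin,
                    prior_sd, scale_resid, scale_intercept,
                    seed = seed + ch - 1L)
  })

  nat <- lapply(draws, natural_scale_draws, domains = domains,
                center = center, scale_ = scale_)
  all_nat <- do.call(rbind, nat)
  rhat <- split_rhat(nat)
  ess <- as.numeric(coda::effectiveSize(
    coda::mcmc.list(lapply(nat, coda::mcmc))))
  qs <- apply(all_nat, 2, stats::quantile, probs = c(0.025, 0.975))
  summ <- data.frame(parameter = colnames(all_nat),
                     mean = colMeans(all_nat),
                     sd = apply(all_nat, 2, stats::sd),
                     q2.5 = qs[1, ], q97.5 = qs[2, ],
                     ess = ess, rhat = rhat,
                     row.names = NULL, stringsAsFactors = FALSE)
  max_rhat <- max(rhat, na.rm = TRUE)
  converged <- max_rhat <= rhat_cutoff
  if (!converged)
    warning(sprintf("MCMC may not have converged: max split-chain Rhat %.3f > %.2f",
                    max_rhat, rhat_cutoff))

  structure(list(call = cl, data = data, flagged = flagged,
                 domains = domains, transform_exponent = 1 / 4,
                 draws = draws, natural_draws = all_nat,
                 center = center, scale = scale_,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 chains = chains, seed = seed, n_draws = n_draws,
                 summary = summ,
                 diagnostics = list(max_rhat = max_rhat, converged = converged,
                                    rhat_cutoff = rhat_cutoff,
                                    n_flagged = nrow(flagged))),
            class = "prevalence_lmm")
}

## internal: map standardized-scale draws to natural covariate scale.
## columns: alpha_<d> (domain intercept mu + a_d mapped back), slopes per
## domain, sigma_e, sigma_domain.
natural_scale_draws <- function(ch, domains, center, scale_) {
  mu <- ch[, "(mu)"]
  out <- matrix(NA_real_, nrow(ch), 3 * length(domains) + 2)
  cn <- c(paste0("intercept_", domains), paste0("slope_medage_", domains),
          paste0("slope_hdi_", domains), "sigma_resid", "sigma_domain")
  colnames(out) <- cn
  for (i in seq_along(domains)) {
    d <- domains[i]
    b1 <- ch[, paste0("b_medage_", d)]
    b2 <- ch[, paste0("b_hdi_", d)]
    a <- ch[, paste0("a_", d)]
    out[, paste0("slope_medage_", d)] <- b1 / scale_[1]
    out[, paste0("slope_hdi_", d)] <- b2 / scale_[2]
    out[, paste0("intercept_", d)] <-
      mu + a - b1 * center[1] / scale_[1] - b2 * center[2] / scale_[2]
  }
  out[, "sigma_resid"] <- sqrt(ch[, "sig_e2"])
  out[, "sigma_domain"] <- sqrt(ch[, "sig_a2"])
  out
}

#' @export
print.prevalence_lmm <- function(x, ...) {
  cat("Fourth-root-scale prevalence mixed model (blocked Gibbs sampler)\n")
  cat(sprintf("  %d observations, %d domains; %d flagged by Cook's-distance screen\n",
              nrow(x$data), length(x$domains), nrow(x$flagged)))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d retained draws\n",
              x$chains, x$n_iter, x$burn_in, x$thin, x$n_draws))
  cat(sprintf("  max split-chain Rhat %.3f (%s)\n", x$diagnostics$max_rhat,
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  cat("\nPosterior means (natural covariate scale):\n")
  print(round(stats::setNames(x$summary$mean, x$summary$parameter), 4))
  invisible(x)
}

#' @export
summary.prevalence_lmm <- function(object, ...) {
  out <- object$summary
  attr(out, "diagnostics") <- object$diagnostics
  class(out) <- c("summary.prevalence_lmm", "data.frame")
  out
}

#' @export
print.summary.prevalence_lmm <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], signif, digits)
  print(df, row.names = FALSE)
  d <- attr(x, "diagnostics")
  cat(sprintf("\nmax Rhat %.3f; %d observation(s) removed by the influence screen\n",
              d$max_rhat, d$n_flagged))
  invisible(x)
}

#' @export
coef.prevalence_lmm <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' @export
fitted.prevalence_lmm <- function(object, ...) {
  lp <- linear_predictor_draws(object, object$data)  # rows x draws
  rowMeans(lp)
}

#' Residuals on the transformed (fourth-root) scale
#' @param object A \code{prevalence_lmm} fit.
#' @param ... Unused.
#' @export
residuals.prevalence_lmm <- function(object, ...) {
  object$data$y - fitted(object)
}

## internal: draws x rows matrix of posterior linear predictors on the
## transformed scale for arbitrary newdata
linear_predictor_draws <- function(object, newdata) {
  check_columns(newdata, c("domain", "median_age", "hdi"), "newdata")
  if (anyNA(newdata$median_age) || anyNA(newdata$hdi)) {
    bad <- unique(newdata$country_id[is.na(newdata$median_age) | is.na(newdata$hdi)])
    abort_at("missing covariates for: ", paste(bad, collapse = ", "))
  }
  unknown <- setdiff(unique(as.character(newdata$domain)), object$domains)
  if (length(unknown))
    abort_at("unknown domain(s): ", paste(unknown, collapse = ", "))
  nat <- object$natural_draws
  d <- as.character(newdata$domain)
  t(vapply(seq_len(nrow(newdata)), function(i) {
    nat[, paste0("intercept_", d[i])] +
      nat[, paste0("slope_medage_", d[i])] * newdata$median_age[i] +
      nat[, paste0("slope_hdi_", d[i])] * newdata$hdi[i]
  }, numeric(nrow(nat))))
}

## internal: quantiles of a normal mixture sum_j N(means_j, sd_j^2)/J,
## computed by root finding (deterministic, order-invariant)
mixture_quantile <- function(means, sds, probs) {
  lo <- min(means) - 8 * max(sds, 1e-12)
  hi <- max(means) + 8 * max(sds, 1e-12)
  vapply(probs, function(p) {
    stats::uniroot(function(q) mean(stats::pnorm(q, means, sds)) - p,
                   lower = lo, upper = hi, tol = 1e-9)$root
  }, 0)
}

#' Predict need prevalence for new countries
#'
#' Forms the posterior (predictive) distribution of the transformed
#' prevalence for each country-domain, summarizes it by the median and the
#' 2.5/97.5 percentiles, verifies the summaries are nonnegative (truncating
#' any negative boundary to zero and counting it), and back-transforms by the
#' fourth power. With \code{interval = "predictive"} (default) the residual
#' observation-level variance is included, giving predictive intervals; with
#' \code{interval = "mean"} only posterior uncertainty in the regression
#' surface is propagated. Both summaries are computed analytically from the
#' retained draws (a normal mixture), so predictions are deterministic and
#' invariant to row order.
#'
#' @param object A \code{prevalence_lmm} fit.
#' @param newdata Data frame with columns \code{country_id}, \code{domain},
#'   \code{median_age}, \code{hdi}.
#' @param interval \code{"predictive"} or \code{"mean"}.
#' @param level Interval level (default 0.95).
#' @param ... Unused.
#'
#' @return Data frame with \code{country_id}, \code{domain}, \code{p_hat},
#'   \code{ci_low}, \code{ci_high} on the natural prevalence scale, and
#'   \code{source = "modeled"}. The number of negative boundaries truncated
#'   to zero is recorded in attribute \code{n_truncated}.
#' @export
predict.prevalence_lmm <- function(object, newdata,
                                   interval = c("predictive", "mean"),
                                   level = 0.95, ...) {
  interval <- match.arg(interval)
  lp <- linear_predictor_draws(object, newdata)
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  sig <- sqrt(object$natural_draws[, "sigma_resid"]^2)
  n_trunc <- 0L
  res <- t(vapply(seq_len(nrow(newdata)), function(i) {
    if (interval == "predictive") {
      q <- mixture_quantile(lp[i, ], sig, probs)
    } else {
      q <- stats::quantile(lp[i, ], probs = probs, names = FALSE)
    }
    q
  }, numeric(3)))
  neg <- res < 0
  n_trunc <- sum(neg)
  res[neg] <- 0
  out <- data.frame(country_id = newdata$country_id,
                    domain = newdata$domain,
                    p_hat = inverse_transform_prevalence(res[, 2]),
                    ci_low = inverse_transform_prevalence(res[, 1]),
                    ci_high = inverse_transform_prevalence(res[, 3]),
                    source = "modeled", stringsAsFactors = FALSE)
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Simulate transformed-scale responses from the posterior predictive
#'
#' Draws replicate response vectors at the fitted design from the posterior
#' predictive distribution (one posterior draw per replicate, plus residual
#' noise), on the transformed \eqn{pN^{1/4}} scale.
#'
#' @param object A \code{prevalence_lmm} fit.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with one column per replicate, \code{nrow(object$data)}
#'   rows.
#' @export
simulate.prevalence_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lp <- linear_predictor_draws(object, object$data)  # rows x draws
  sig <- object$natural_draws[, "sigma_resid"]
  j <- sample.int(ncol(lp), nsim, replace = TRUE)
  out <- vapply(j, function(jj) lp[, jj] + stats::rnorm(nrow(lp), 0, sig[jj]),
                numeric(nrow(lp)))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Trace and diagnostic plot for a prevalence model fit
#'
#' Plots MCMC traces for the residual and domain-intercept standard
#' deviations and a residual-vs-fitted panel on the transformed scale.
#'
#' @param x A \code{prevalence_lmm} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.prevalence_lmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  nat <- lapply(x$draws, natural_scale_draws, domains = x$domains,
                center = x$center, scale_ = x$scale)
  for (parm in c("sigma_resid", "sigma_domain")) {
    graphics::plot(nat[[1]][, parm], type = "l", xlab = "retained draw",
                   ylab = parm, main = paste("trace:", parm), ...)
    if (length(nat) > 1)
      for (ch in nat[-1]) graphics::lines(ch[, parm], col = "grey60")
  }
  graphics::plot(fitted(x), residuals(x), xlab = "fitted (y scale)",
                 ylab = "residual", main = "residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
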