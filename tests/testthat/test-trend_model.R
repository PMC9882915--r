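# The coverage trend model: mixture marginalization, prediction transforms,
# odds ratios, recovery on synthetic data, posterior predictive checking.

test_that("stratum probabilities marginalize serostatus exactly", {
  # pinned arithmetic: p_neg = 0.1, log-OR = ln 2, pi = 0.2
  params <- list(beta0 = qlogis(0.1), gamma = log(2))
  cov_all <- list(year = 2010, age_group = "25-29", recall = "lifetime",
                  hiv = "all")
  expect_equal(stratum_probability(params, cov_all, prevalence = 0.2),
               0.2 * (2 / 11) + 0.8 * 0.1)
  expect_equal(stratum_probability(params, cov_all, prevalence = 1),
               stratum_probability(params, modifyList(cov_all,
                                                      list(hiv = "pos"))))
  # gamma terms all zero: mixture collapses for any prevalence
  p0 <- list(beta0 = 0.3)
  expect_equal(stratum_probability(p0, cov_all, prevalence = 0.77),
               stratum_probability(p0, modifyList(cov_all,
                                                  list(hiv = "neg"))))
  expect_error(stratum_probability(params, cov_all), "prevalence")
})

test_that("mixture identity holds to 1e-12 over random draws", {
  set.seed(31)
  for (i in 1:2000) {
    params <- list(beta0 = rnorm(1, 0, 2), u_region = rnorm(1, 0, 0.5),
                   u_country = rnorm(1, 0, 0.5), u_survey = rnorm(1, 0, 0.3),
                   alpha_age = c("30-34" = rnorm(1)),
                   beta_year = rnorm(1), v_region = rnorm(1, 0, 0.2),
                   v_country = rnorm(1, 0, 0.2),
                   beta_recall = -abs(rnorm(1)), gamma = rnorm(1),
                   g_region = rnorm(1, 0, 0.3), g_country = rnorm(1, 0, 0.3))
    covs <- list(year = runif(1, 2000, 2020), age_group = "30-34",
                 recall = sample(c("lifetime", "past3y"), 1), hiv = "all")
    pi_ <- runif(1)
    p_pos <- stratum_probability(params, modifyList(covs,
                                                    list(hiv = "pos")))
    p_neg <- stratum_probability(params, modifyList(covs,
                                                    list(hiv = "neg")))
    p_all <- stratum_probability(params, covs, prevalence = pi_)
    expect_lt(abs(p_all - (pi_ * p_pos + (1 - pi_) * p_neg)), 1e-12)
  }
})

test_that("prediction is the exact deterministic transform of the draws", {
  # all parameters zero -> coverage 1/2 everywhere
  post <- fake_trend_posterior(D = 3)
  grid <- expand.grid(country = c("GHA", "KEN"), year = c(2005, 2015),
                      age_group = c("25-29", "45-49"),
                      hiv = c("pos", "neg"), recall = c("lifetime", "past3y"),
                      stringsAsFactors = FALSE)
  cov <- predict_coverage(post, grid)
  expect_true(all(cov$draws == 0.5))
  # hand-built draw: b0 = logit(0.1), HIV log-OR = ln 2
  post2 <- fake_trend_posterior(D = 2, overrides = list(
    "a_c[1]" = qlogis(0.1), "a_c[2]" = qlogis(0.1),
    "g_c[1]" = log(2), "g_c[2]" = log(2)))
  cov2 <- predict_coverage(post2, grid)
  expect_equal(unique(as.vector(cov2$draws[, grid$hiv == "neg"])), 0.1)
  expect_equal(unique(as.vector(cov2$draws[, grid$hiv == "pos"])), 2 / 11,
               tolerance = 1e-12)
  # recall offset -0.3: past3y strictly below lifetime, draw-wise
  post3 <- fake_trend_posterior(D = 5, overrides = list(b_recall = -0.3))
  cov3 <- predict_coverage(post3, grid)
  life <- cov3$draws[, grid$recall == "lifetime"]
  p3y <- cov3$draws[, grid$recall == "past3y"]
  expect_true(all(p3y < life))
  expect_error(predict_coverage(post, transform(grid, country = "MOZ")),
               "MOZ")
})

test_that("HIV odds ratios summarize the slope draws", {
  post <- fake_trend_posterior(D = 10, overrides = list(
    gam = log(2), "g_r[1]" = log(2), "g_c[1]" = log(2)))
  or <- hiv_odds_ratio(post, country = "GHA")
  expect_equal(or$summary$median, 2)
  expect_equal(or$summary$hi95 - or$summary$lo95, 0)
  # degenerate hierarchy: country OR equals the global OR draw-wise
  expect_equal(hiv_odds_ratio(post, country = "GHA")$draws,
               hiv_odds_ratio(post)$draws)
  # lognormal draws: quantiles match the closed form
  set.seed(8)
  lor <- rnorm(10000, log(2), 0.1)
  post2 <- fake_trend_posterior(D = 10000, overrides = list(gam = lor))
  s <- hiv_odds_ratio(post2)$summary
  expect_equal(s$median, 2, tolerance = 0.01)
  expect_equal(s$lo95, exp(log(2) - 1.959964 * 0.1), tolerance = 0.02)
  expect_equal(s$hi95, exp(log(2) + 1.959964 * 0.1), tolerance = 0.02)
})

test_that("the fitted model recovers the generating fixed effects", {
  sh <- shared_trend_fit()
  fit <- sh$fit
  expect_s3_class(fit, "trend_posterior")
  expect_true(all(fit$rhat <= 1.05, na.rm = TRUE))
  expect_true(all(fit$draws[, "b_recall"] <= 0))
  sds <- fit$draws[, c("sig_s", "sig_c", "sig_r", "tau_c", "tau_r",
                       "om_c", "om_r")]
  expect_true(all(sds > 0))
  ci <- quantile(fit$draws[, "b_year"], c(0.025, 0.975))
  expect_lt(ci[1], 0.5); expect_gt(ci[2], 0.5)
  ci_or <- quantile(exp(fit$draws[, "gam"]), c(0.025, 0.975))
  expect_lt(ci_or[1], 2); expect_gt(ci_or[2], 2)
  # predictions stay inside (0,1) and respect the recall ordering
  grid <- prediction_grid(fit$countries$country, years = c(2005, 2020))
  cov <- predict_coverage(fit, grid)
  expect_true(all(cov$draws > 0 & cov$draws < 1))
  m <- match(paste(grid$country, grid$year, grid$age_group, grid$hiv,
                   "past3y"),
             paste(grid$country, grid$year, grid$age_group, grid$hiv,
                   grid$recall))
  life_cols <- which(grid$recall == "lifetime")
  expect_true(all(cov$draws[, m[life_cols]] < cov$draws[, life_cols]))
})

test_that("zero-information strata do not perturb the posterior", {
  sh <- shared_trend_fit()
  strata2 <- rbind(sh$strata,
                   transform(sh$strata[1, ], k_eff = 0, n_eff = 0.4))
  cfg <- mcmc_config(chains = 2, warmup = 300, iter = 200, seed = 5)
  f1 <- suppressWarnings(fit_trend_model(sh$strata, sh$aux, cfg))
  f2 <- suppressWarnings(fit_trend_model(strata2, sh$aux, cfg))
  expect_identical(f1$draws, f2$draws)
})

test_that("an unidentified HIV slope returns its prior", {
  # no serostatus information anywhere and prevalence identically zero
  w <- flat_world(beta0 = qlogis(0.15), prevalence = 0)
  des <- default_survey_design(w)
  des$sero_reported <- FALSE
  strata <- simulate_surveys(w, des, seed = 14)
  aux <- simulate_aux_tables(w)
  fit <- suppressWarnings(fit_trend_model(
    strata, aux, mcmc_config(chains = 2, warmup = 500, iter = 2000,
                             thin = 5, seed = 11)))
  ks <- suppressWarnings(
    stats::ks.test(fit$draws[, "gam"], pnorm, 0, 2.5))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("posterior predictive checks calibrate and flag gross misfit", {
  sh <- shared_trend_fit()
  ppc <- posterior_predictive_check(sh$fit, seed = 3)
  expect_gte(ppc$prop_inside, 0.90)
  expect_lte(ppc$prop_inside, 0.99)
  # replacing observations by their own predictive centers -> all inside
  post_med <- sh$fit
  p_mean <- colMeans(ccscreen:::stratum_p_draws(sh$fit))
  post_med$data$jags$k <- as.integer(round(post_med$data$jags$n * p_mean))
  ppc_med <- posterior_predictive_check(post_med, seed = 4)
  expect_equal(ppc_med$prop_inside, 1)
  # corrupting one stratum's count to its denominator is flagged
  post_bad <- sh$fit
  i_low <- which.min(post_bad$data$jags$k / post_bad$data$jags$n)
  post_bad$data$jags$k[i_low] <- post_bad$data$jags$n[i_low]
  ppc_bad <- posterior_predictive_check(post_bad, seed = 5)
  expect_false(ppc_bad$strata$inside[i_low])
  expect_gt(abs(ppc_bad$strata$z[i_low]), 4)
})

test_that("posterior and coverage draws persist as long CSV", {
  sh <- shared_trend_fit()
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_posterior(sh$fit, p1)
  long <- read.csv(p1)
  expect_setequal(names(long), c("draw", "parameter", "value"))
  expect_equal(nrow(long), nrow(sh$fit$draws) * ncol(sh$fit$draws))
  grid <- prediction_grid("KEN", years = 2020)
  cov <- predict_coverage(sh$fit, grid)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_coverage_draws(cov, p2)
  back <- read.csv(p2)
  expect_equal(nrow(back), nrow(grid) * nrow(cov$draws))
  expect_true(all(back$p > 0 & back$p < 1))
})
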