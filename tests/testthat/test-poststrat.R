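# Post-stratification: weights, aggregation, country imputation.

make_aux <- function(pop, prev, countries = "GHA", years = 2010,
                     ages = c("30-34", "35-39")) {
  grid <- expand.grid(country = countries, year = years, age_group = ages,
                      stringsAsFactors = FALSE)
  aux_tables(cbind(grid, pop_f = pop), cbind(grid, prev = prev))
}

test_that("weights are population-times-prevalence shares", {
  # pops (200000, 100000), prevalence (0.2, 0.1):
  # (pos30, neg30, pos35, neg35) = (40, 160, 10, 90)/300
  aux <- make_aux(pop = c(2e5, 1e5), prev = c(0.2, 0.1))
  w <- build_weights(aux, aggregate_spec("agg", "GHA", 2010,
                                         c("30-34", "35-39")))
  key <- paste(w$age_group, w$hiv)
  expect_equal(w$weight[match("30-34 pos", key)], 40 / 300)
  expect_equal(w$weight[match("30-34 neg", key)], 160 / 300)
  expect_equal(w$weight[match("35-39 pos", key)], 10 / 300)
  expect_equal(w$weight[match("35-39 neg", key)], 90 / 300)
  expect_equal(sum(w$weight), 1)
  # prevalence zero: all mass on the hiv-negative strata
  aux0 <- make_aux(pop = c(1e5, 1e5), prev = c(0, 0))
  w0 <- build_weights(aux0, aggregate_spec("agg", "GHA", 2010,
                                           c("30-34", "35-39")))
  expect_equal(w0$weight[w0$hiv == "pos"], c(0, 0))
  expect_equal(w0$weight[w0$hiv == "neg"], c(0.5, 0.5))
  # one-stratum aggregate gets weight 1
  w1 <- build_weights(aux0, aggregate_spec("one", "GHA", 2010, "30-34",
                                           hiv = "neg"))
  expect_equal(w1$weight, 1)
  expect_error(build_weights(aux0, aggregate_spec("x", "KEN", 2010,
                                                  "30-34")),
               "KEN")
})

fake_coverage <- function(countries, years, ages, D = 50, seed = 2) {
  grid <- expand.grid(country = countries, year = years, age_group = ages,
                      hiv = c("pos", "neg"), recall = "lifetime",
                      stringsAsFactors = FALSE)
  set.seed(seed)
  structure(list(grid = grid,
                 draws = matrix(runif(D * nrow(grid), 0.05, 0.95), D)),
            class = "coverage_draws")
}

test_that("aggregates are convex combinations of their strata", {
  aux <- make_aux(pop = c(2e5, 1e5), prev = c(0.2, 0.1))
  cov <- fake_coverage("GHA", 2010, c("30-34", "35-39"))
  w <- build_weights(aux, aggregate_spec("agg", "GHA", 2010,
                                         c("30-34", "35-39")))
  agg <- aggregate_draws(cov, w)
  a <- agg$draws[["agg|2010|lifetime"]]
  expect_true(all(a >= apply(cov$draws, 1, min) - 1e-12))
  expect_true(all(a <= apply(cov$draws, 1, max) + 1e-12))
  # two-stratum pinned example: p = (0.1, 0.3), w = (0.25, 0.75) -> 0.25
  cov2 <- fake_coverage("GHA", 2010, c("30-34", "35-39"), D = 1)
  cov2$grid <- cov2$grid[cov2$grid$hiv == "neg", ]
  cov2$draws <- matrix(c(0.1, 0.3), 1)
  w2 <- data.frame(aggregate = "two", year = 2010, country = "GHA",
                   age_group = c("30-34", "35-39"), hiv = "neg",
                   weight = c(0.25, 0.75))
  expect_equal(aggregate_draws(cov2, w2)$draws[["two|2010|lifetime"]],
               0.25)
  # constant draw is a fixed point
  cov3 <- cov
  cov3$draws[] <- 0.3
  expect_equal(unique(aggregate_draws(cov3, w)$draws[[1]]), 0.3)
})

test_that("nested aggregation equals direct aggregation", {
  countries <- c("GHA", "NGA")
  aux <- make_aux(pop = c(3e5, 1e5, 2e5, 2e5), prev = 0.1,
                  countries = countries)
  cov <- fake_coverage(countries, 2010, c("30-34", "35-39"), D = 200)
  # step 1: country aggregates; step 2: combine with population shares
  w_gha <- build_weights(aux, aggregate_spec("GHA", "GHA", 2010,
                                             c("30-34", "35-39")))
  w_nga <- build_weights(aux, aggregate_spec("NGA", "NGA", 2010,
                                             c("30-34", "35-39")))
  a_gha <- aggregate_draws(cov, w_gha)$draws[[1]]
  a_nga <- aggregate_draws(cov, w_nga)$draws[[1]]
  pop_gha <- 5e5; pop_nga <- 3e5  # column totals of the aux grid
  two_step <- (pop_gha * a_gha + pop_nga * a_nga) / (pop_gha + pop_nga)
  w_all <- build_weights(aux, aggregate_spec("ALL", countries, 2010,
                                             c("30-34", "35-39")))
  direct <- aggregate_draws(cov, w_all)$draws[[1]]
  expect_lt(max(abs(two_step - direct)), 1e-10)
})

test_that("aggregation is invariant to splitting a stratum in half", {
  cov <- fake_coverage("GHA", 2010, c("30-34", "35-39"), D = 20)
  w <- data.frame(aggregate = "a", year = 2010, country = "GHA",
                  age_group = c("30-34", "35-39"), hiv = "neg",
                  weight = c(0.4, 0.6))
  w_split <- rbind(w, w[1, ])
  w_split$weight <- c(0.2, 0.6, 0.2)
  expect_equal(aggregate_draws(cov, w)$draws[[1]],
               aggregate_draws(cov, w_split)$draws[[1]])
})

test_that("imputed countries inherit the region mean plus country spread", {
  grid <- data.frame(year = 2010, age_group = "30-34", hiv = "neg",
                     recall = "lifetime")
  # degenerate hierarchy: imputation reproduces the region prediction
  post0 <- fake_trend_posterior(D = 100, overrides = list(
    "a_r[1]" = qlogis(0.2), "a_r[2]" = qlogis(0.4)))
  imp0 <- impute_country(post0, "Eastern Africa", grid, country = "XXX",
                         seed = 3)
  expect_equal(unique(round(imp0$draws[, 1], 9)), 0.2)
  # sig_c = 0.5: logit-scale variance adds 0.25 over the region variance
  set.seed(5)
  a_r <- rnorm(4000, qlogis(0.3), 0.3)
  post1 <- fake_trend_posterior(D = 4000, overrides = list(
    "a_r[1]" = a_r, sig_c = 0.5))
  imp1 <- impute_country(post1, "Eastern Africa", grid, seed = 4)
  v_region <- var(a_r)
  v_imp <- var(qlogis(imp1$draws[, 1]))
  expect_equal(v_imp, v_region + 0.25, tolerance = 0.1 * (v_region + 0.25))
  # reproducible given the seed
  imp2 <- impute_country(post1, "Eastern Africa", grid, seed = 4)
  expect_identical(imp1$draws, imp2$draws)
  expect_error(impute_country(post1, "Mars", grid), "Mars")
})

test_that("imputation carries wider intervals than observed countries", {
  sh <- shared_trend_fit()
  grid <- prediction_grid("KEN", years = c(2005, 2015))
  obs <- predict_coverage(sh$fit, grid)
  igrid <- grid[setdiff(names(grid), "country")]
  imp <- impute_country(sh$fit, "Eastern Africa", igrid, country = "MWI",
                        seed = 9)
  so <- summary(obs); si <- summary(imp)
  expect_gt(mean(si$hi95 - si$lo95 > so$hi95 - so$lo95), 0.95)
})

test_that("country data tiers follow the survey count", {
  sh <- shared_trend_fit()
  expect_identical(country_data_tier(sh$strata, "KEN"), ">=2 surveys")
  expect_identical(country_data_tier(sh$strata[sh$strata$survey_id ==
                                                 "KEN-2008", ], "KEN"),
                   "1 survey")
  expect_identical(country_data_tier(sh$strata, "MWI"), "imputed")
})
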