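# Rate-ratio inputs, the multistate life table, and the S3-rate inversion.

test_that("age-increment records reproduce the crude moment estimator", {
  base <- data.frame(
    survey_id = "s1", country = "KEN", region = "Eastern Africa",
    survey_type = "OTHER", year = 2015, hiv = "neg",
    stringsAsFactors = FALSE)
  obs <- rbind(
    transform(base, age_group = "25", recall = "lifetime", k_eff = 100,
              n_eff = 1000),
    transform(base, age_group = "26", recall = "lifetime", k_eff = 120,
              n_eff = 1000),
    transform(base, age_group = "25", recall = "past1y", k_eff = 50,
              n_eff = 1000))
  inp <- build_rate_ratio_inputs(obs, c(25, 25))
  # L(25)=0.10, L(26)=0.12, P=0.05 -> q1=0.0222, qre=0.30, RR ~ 15.9
  expect_equal(inp$q1, 0.02 / 0.9)
  expect_equal(inp$qre, 0.3)
  expect_equal(inp$rr_crude, log(0.7) / log(1 - 0.02 / 0.9))
  expect_equal(round(inp$rr_crude, 1), 15.9)
  expect_true(inp$ok)
  # past-year equal to the increment: no re-screening, RR = 0
  obs2 <- obs
  obs2$k_eff[3] <- 20
  expect_equal(build_rate_ratio_inputs(obs2, c(25, 25))$rr_crude, 0)
  # empty risk set (L(a) = 0) is flagged
  obs3 <- obs
  obs3$k_eff[1] <- 0
  inp3 <- build_rate_ratio_inputs(obs3, c(25, 25))
  expect_false(inp3$ok)
  expect_true(is.na(inp3$rr_crude))
  # negative increment is flagged but retained
  obs4 <- obs
  obs4$k_eff[2] <- 80
  inp4 <- build_rate_ratio_inputs(obs4, c(25, 25))
  expect_false(inp4$ok)
  expect_equal(nrow(inp4), 1)
})

test_that("the S3 inversion round-trips through the defining equation", {
  expect_equal(solve_screening_rates(0, 0.5, 10)$r1, 0)
  s <- solve_screening_rates(
    0.6 * (1 - exp(-0.15)) + 0.4 * (1 - exp(-1.5)), 0.6, 10)
  expect_lt(abs(s$r1 - 0.05), 1e-8)
  expect_equal(s$r2, 10 * s$r1)
  # monotone in S3
  r_lo <- solve_screening_rates(0.1, 0.6, 10)$r1
  r_hi <- solve_screening_rates(0.3, 0.6, 10)$r1
  expect_gt(r_hi, r_lo)
  # clamping flag at the supremum
  expect_true(solve_screening_rates(1, 0.5, 2)$clamped)
})

test_that("the life table matches its closed forms", {
  # zero rates: nothing moves
  lt0 <- run_life_table(0, 0, cycles = 15)
  expect_equal(lt0$S0, rep(1, 16))
  expect_equal(lt0$S2[16], 0)
  # constant r1=0.05, RR=10: linear-recurrence closed form to 1e-10
  lt <- run_life_table(0.05, 0.5, cycles = 15)
  b <- exp(-0.05); a <- exp(-0.5); p1 <- 1 - exp(-0.05)
  expect_equal(lt$S0[16], exp(-0.75), tolerance = 1e-10)
  expect_equal(lt$S1[16], p1 * (b^15 - a^15) / (b - a), tolerance = 1e-10)
  expect_equal(lt$S2[16], 1 - exp(-0.75) - p1 * (b^15 - a^15) / (b - a),
               tolerance = 1e-10)
  # RR = 1: ever screened is geometric survival
  lt1 <- run_life_table(0.08, 0.08, cycles = 10)
  expect_equal(1 - lt1$S0, 1 - exp(-0.08 * (0:10)), tolerance = 1e-12)
})

test_that("life-table invariants hold over random rate paths", {
  set.seed(77)
  for (i in 1:25) {
    cycles <- sample(5:20, 1)
    r1 <- runif(cycles, 0, 0.5)
    r2 <- runif(cycles, 0, 2)
    init <- c(0.7, 0.2, 0.1)
    lt <- run_life_table(r1, r2, init = init, cycles = cycles)
    expect_true(all(abs(lt$S0 + lt$S1 + lt$S2 - 1) < 1e-12))
    expect_true(all(diff(lt$S0) <= 1e-15))
    expect_true(all(diff(lt$S2) >= -1e-15))
    expect_true(all(lt$S0 >= 0 & lt$S1 >= 0 & lt$S2 >= 0))
  }
})

test_that("the life table agrees with the microsimulation oracle", {
  h <- simulate_histories(0.05, 10, 50000, 15, seed = 19)
  occ <- history_occupancy(h, 1:15)
  lt <- run_life_table(0.05, 0.5, cycles = 15)
  for (t in 1:15) for (s in c("S0", "S1", "S2")) {
    p <- lt[[s]][t + 1]
    se <- sqrt(max(p * (1 - p), 1e-12) / 50000)
    expect_lt(abs(occ[[s]][t] - p), 3 * se + 1e-12)
  }
})

test_that("screened-twice summaries report both proportions", {
  # constant-rate pinned values
  lt <- run_life_table(0.05, 0.5, cycles = 15)
  tables <- array(NA_real_, c(2, 16, 3),
                  dimnames = list(NULL, NULL, c("S0", "S1", "S2")))
  for (d in 1:2) tables[d, , ] <- as.matrix(lt[c("S0", "S1", "S2")])
  s <- screened_twice_summary(list(tables = tables, ages = 30:45))
  expect_equal(s$median[1], 0.4608777, tolerance = 1e-6)
  expect_equal(s$median[2], 0.4608777 / (1 - exp(-0.75)), tolerance = 1e-4)
  # two identical draws: zero-width interval
  expect_equal(s$lo95, s$hi95)
  # no screening: conditional proportion is not applicable
  lt0 <- run_life_table(0, 0, cycles = 15)
  t0 <- array(rep(as.matrix(lt0[c("S0", "S1", "S2")]), each = 1),
              c(1, 16, 3), dimnames = list(NULL, NULL, c("S0", "S1", "S2")))
  s0 <- screened_twice_summary(list(tables = t0, ages = 30:45))
  expect_equal(s0$median[1], 0)
  expect_true(is.na(s0$median[2]))
})

test_that("the Bayesian rate-ratio model recovers stationary truths", {
  inp20 <- make_rate_ratio_inputs(20, seed = 1)
  fit20 <- suppressWarnings(fit_rate_ratio(
    inp20, mcmc_config(chains = 3, warmup = 2000, iter = 1000, thin = 10,
                       seed = 2)))
  expect_true(all(fit20$rhat < 1.05, na.rm = TRUE))
  rr <- rate_ratio_draws(fit20, "Western/Central/Eastern Africa")
  expect_true(all(rr > 0))
  ci <- quantile(rr, c(0.025, 0.975))
  expect_lt(ci[1], 20); expect_gt(ci[2], 20)
  # crude moment estimator agrees in magnitude
  expect_equal(median(inp20$rr_crude[inp20$ok], na.rm = TRUE), 20,
               tolerance = 0.35)
  # a region label is accepted and mapped to its group
  expect_identical(rate_ratio_draws(fit20, "Eastern Africa"), rr)
  expect_error(rate_ratio_draws(fit20, "Southern Africa"), "Southern")
})

test_that("cohort life tables are coherent with a hazard-law coverage surface", {
  # build coverage draws directly from a constant-hazard world, so the
  # S3 inversion and the life table must reproduce the lifetime curve
  r1 <- 0.03; RR <- 8; start_age <- 30; start_year <- 2005
  L <- function(age) 1 - exp(-r1 * (age - 15))
  years <- start_year + 0:15
  ages <- start_age + 0:15
  grid <- do.call(rbind, lapply(0:15, function(t) {
    band <- AGE_BANDS_5Y[findInterval(ages[t + 1],
                                      c(25, 30, 35, 40, 45, 50))]
    data.frame(country = "KEN", year = years[t + 1], age_group = band,
               hiv = "neg", recall = c("lifetime", "past3y"))
  }))
  grid <- unique(grid)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    age <- 30 + grid$year[i] - 2005
    S0 <- exp(-r1 * (age - 15))
    if (grid$recall[i] == "lifetime") 1 - S0
    else  # window equation at the cohort's current never-screened fraction
      S0 * (1 - exp(-3 * r1)) + (1 - S0) * (1 - exp(-3 * RR * r1))
  }, numeric(1L))
  cov <- structure(list(grid = grid, draws = matrix(p, 2, nrow(grid),
                                                    byrow = TRUE)),
                   class = "coverage_draws")
  lt <- cohort_life_tables(cov, rr_draws = RR, country = "KEN",
                           start_age = 30, start_year = 2005,
                           init = "model")
  ever_lt <- unname(1 - lt$tables[1, 16, "S0"])
  expect_equal(ever_lt, L(45), tolerance = 0.01)
  chk <- lifetable_vs_trend(lt, cov)
  expect_lt(chk$median_abs_discrepancy, 0.05)
  # naive initialization starts everyone unscreened
  lt_naive <- cohort_life_tables(cov, RR, "KEN", init = "naive")
  expect_equal(unname(lt_naive$tables[1, 1, "S0"]), 1)
  expect_lt(lt_naive$tables[1, 16, "S2"], lt$tables[1, 16, "S2"] + 1e-9)
})
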