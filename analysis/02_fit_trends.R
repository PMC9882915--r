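#!/usr/bin/env Rscript
# Stage 2 — fit the four-level coverage trend model to the simulated survey
# strata, check convergence and posterior predictive calibration, and
# persist posterior and coverage draws.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

aux <- load_aux_tables(data_path("population.csv"),
                       data_path("prevalence.csv"))
strata <- load_strata(data_path("strata.csv"), aux = aux)

fit <- fit_trend_model(strata, aux, stage_mcmc(),
                       year_min = cfg$sensitivity$year_min,
                       whs_effect = isTRUE(cfg$sensitivity$whs_fixed_effect))
if (!fit$converged) {
  message("Convergence failure (max split-Rhat ",
          round(max(fit$rhat, na.rm = TRUE), 3), "); see diagnostics")
  quit(status = 3)
}
print(fit)

ppc <- posterior_predictive_check(fit, seed = cfg$seed + 2000L)
message(sprintf("Posterior predictive check: %.1f%% of %d strata inside ",
                100 * ppc$prop_inside, nrow(ppc$strata)),
        "their central 95% predictive intervals")

write_posterior(fit, path_of("trend_posterior.csv"))
# persist draws for the reporting years only; later stages recompute any
# denser grids they need from the posterior
grid <- prediction_grid(fit$countries$country,
                        years = c(2000, 2010, 2020))
coverage <- predict_coverage(fit, grid)
write_coverage_draws(coverage, path_of("coverage_draws.csv"))
write.csv(ppc$strata, path_of("ppc_report.csv"), row.names = FALSE)

or_tab <- do.call(rbind, c(
  list(cbind(unit = "sub-Saharan Africa", hiv_odds_ratio(fit)$summary)),
  lapply(fit$regions, function(r)
    cbind(unit = r, hiv_odds_ratio(fit, region = r)$summary)),
  lapply(fit$countries$country, function(cc)
    cbind(unit = cc, hiv_odds_ratio(fit, country = cc)$summary))))
write.csv(or_tab, path_of("hiv_odds_ratios.csv"), row.names = FALSE)
message("Adjusted HIV odds ratios (screening, WLHIV vs HIV-negative):")
print(or_tab, row.names = FALSE)

write_manifest("fit-trends", cfg, cfg$seed,
               artifacts = c(path_of("trend_posterior.csv"),
                             path_of("coverage_draws.csv"),
                             path_of("ppc_report.csv"),
                             path_of("hiv_odds_ratios.csv")),
               upstream = path_of("manifest_simulate.json"),
               diagnostics = list(max_split_rhat = max(fit$rhat, na.rm = TRUE),
                                  ppc_prop_inside = ppc$prop_inside),
               path = path_of("manifest_fit_trends.json"))
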