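#!/usr/bin/env Rscript
# Stage 3 — post-stratify coverage draws to the reporting aggregates:
# women 30-49 by region and for all of sub-Saharan Africa (serostatus
# combined), and WLHIV 25-49; countries without surveys are imputed from
# the fitted hierarchy and included in the regional aggregates with their
# population weights.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

aux <- load_aux_tables(data_path("population.csv"),
                       data_path("prevalence.csv"))
strata <- load_strata(data_path("strata.csv"), aux = aux)
fit <- fit_trend_model(strata, aux, stage_mcmc(),
                       year_min = cfg$sensitivity$year_min,
                       whs_effect = isTRUE(cfg$sensitivity$whs_fixed_effect))

years <- c(2000, 2010, 2020)
ages_3049 <- c("30-34", "35-39", "40-44", "45-49")
observed <- fit$countries$country
coverage <- predict_coverage(fit, prediction_grid(observed, years))

# impute one demonstration no-survey country per region and fold it into
# the aggregates with its own population weight
imputed <- list("Western/Central Africa" = "SEN",
                "Eastern Africa" = "MWI",
                "Southern Africa" = "NAM")
aux_imp <- aux
for (r in names(imputed)) {
  cc <- imputed[[r]]
  gr <- expand.grid(country = cc, year = years, age_group = AGE_BANDS_5Y,
                    stringsAsFactors = FALSE)
  aux_imp$population <- rbind(aux_imp$population,
                              cbind(gr, pop_f = 1e5))
  aux_imp$prevalence <- rbind(aux_imp$prevalence,
                              cbind(gr, prev = mean(aux$prevalence$prev)))
}
imp_cov <- lapply(names(imputed), function(r)
  impute_country(fit, r, prediction_grid("X", years)[-1],
                 country = imputed[[r]], seed = cfg$seed + 400L +
                   match(r, names(imputed))))
all_cov <- do.call(bind_coverage, c(list(coverage), imp_cov))

region_members <- split(c(observed, unlist(imputed)),
                        map_country_to_region(c(observed,
                                                unlist(imputed))))
specs <- c(
  lapply(names(region_members), function(r)
    aggregate_spec(r, region_members[[r]], years, ages_3049)),
  list(aggregate_spec("sub-Saharan Africa", unlist(region_members), years,
                      ages_3049),
       aggregate_spec("WLHIV 25-49", unlist(region_members), years,
                      AGE_BANDS_5Y, hiv = "pos")))
summaries <- do.call(rbind, lapply(specs, function(sp)
  aggregate_draws(all_cov, build_weights(aux_imp, sp))$summary))
write.csv(summaries, path_of("aggregates.csv"), row.names = FALSE)
message("Post-stratified aggregates (proportion screened):")
print(summaries, row.names = FALSE, digits = 3)

tiers <- data.frame(country = c(observed, unlist(imputed)))
tiers$tier <- vapply(tiers$country, function(cc)
  country_data_tier(strata, cc), character(1L))
write.csv(tiers, path_of("country_tiers.csv"), row.names = FALSE)

write_manifest("poststratify", cfg, cfg$seed,
               artifacts = c(path_of("aggregates.csv"),
                             path_of("country_tiers.csv")),
               upstream = path_of("manifest_fit_trends.json"),
               path = path_of("manifest_poststratify.json"))
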