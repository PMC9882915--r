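#!/usr/bin/env Rscript
# Stage 6 — validation: recompute the ground truth from (config, seed) and
# compare it with the fitted pipeline; check posterior predictive
# calibration, credible-interval coverage of the generating fixed effects,
# rate-ratio recovery, and the life-table/trend-model consistency.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

world <- make_world(world_config(), seed = cfg$seed)
aux <- load_aux_tables(data_path("population.csv"),
                       data_path("prevalence.csv"))
strata <- load_strata(data_path("strata.csv"), aux = aux)
fit <- fit_trend_model(strata, aux, stage_mcmc())
ppc <- posterior_predictive_check(fit, seed = cfg$seed + 2000L)

ci <- apply(fit$draws[, c("b_year", "gam", "b_recall")], 2, quantile,
            c(0.025, 0.975))
truth <- c(b_year = world$config$beta_year, gam = world$config$gamma,
           b_recall = world$config$beta_recall)
checks <- data.frame(
  check = c("max split-Rhat <= 1.05",
            "95% CrI covers true year slope",
            "95% CrI covers true HIV log-OR",
            "95% CrI covers true recall offset",
            "PPC: 90-99% of strata inside 95% intervals"),
  value = c(max(fit$rhat, na.rm = TRUE),
            truth["b_year"], truth["gam"], truth["b_recall"],
            ppc$prop_inside),
  passed = c(max(fit$rhat, na.rm = TRUE) <= 1.05,
             vapply(names(truth), function(p)
               ci[1, p] <= truth[p] && truth[p] <= ci[2, p],
               logical(1L)),
             ppc$prop_inside >= 0.90 && ppc$prop_inside <= 0.99))

rr_strata <- load_strata(data_path("rate_ratio_strata.csv"))
rr_fit <- fit_rate_ratio(build_rate_ratio_inputs(rr_strata),
                         stage_mcmc(5L))
for (g in rr_fit$groups) {
  d <- rate_ratio_draws(rr_fit, g)
  tr <- world$config$rr[[g]]
  checks <- rbind(checks, data.frame(
    check = paste0("95% CrI covers true rate ratio (", g, ")"),
    value = tr,
    passed = quantile(d, 0.025) <= tr && tr <= quantile(d, 0.975)))
}

write.csv(checks, path_of("validation.csv"), row.names = FALSE)
print(checks, row.names = FALSE, digits = 3)
if (!all(checks$passed)) {
  message("validation FAILED")
  quit(status = 3)
}
message("All validation checks passed.")
write_manifest("validate", cfg, cfg$seed,
               artifacts = path_of("validation.csv"),
               upstream = c(path_of("manifest_simulate.json"),
                            path_of("manifest_fit_trends.json")),
               path = path_of("manifest_validate.json"))
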