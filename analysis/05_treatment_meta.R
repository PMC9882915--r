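#!/usr/bin/env Rscript
# Stage 5 — Bayesian random-effects meta-analysis of pre-cancer treatment
# coverage among women with an abnormal, non-cancer screening result.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

treatment <- load_treatment(data_path("treatment.csv"))
fit <- fit_treatment_meta(treatment, stage_mcmc(9L))

summary_tab <- rbind(pooled_estimate(fit),
                     pooled_estimate(fit, type = "population"),
                     country_estimates(fit))
write.csv(summary_tab, path_of("treatment_coverage.csv"),
          row.names = FALSE)
message("Pre-cancer treatment coverage:")
print(summary_tab, row.names = FALSE, digits = 3)

write_manifest("treatment-meta", cfg, cfg$seed,
               artifacts = path_of("treatment_coverage.csv"),
               upstream = path_of("manifest_simulate.json"),
               diagnostics = list(
                 max_split_rhat = max(fit$rhat, na.rm = TRUE)),
               path = path_of("manifest_treatment.json"))
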