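#!/usr/bin/env Rscript
# Stage 1 — simulate every pipeline input with known ground truth: the true
# coverage world, survey tabulations, auxiliary population/prevalence
# tables, single-year-age cross-sections of screening histories (for the
# rate-ratio model) and treatment tabulations.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_common.R"))

world <- make_world(world_config(), seed = cfg$seed)
message("True world: beta_year = ", world$config$beta_year,
        "/decade, HIV OR = ", round(exp(world$config$gamma), 2),
        ", recall offset = ", world$config$beta_recall)

strata <- simulate_surveys(world, default_survey_design(world),
                           seed = cfg$seed + 1000L)
write_strata(strata, data_path("strata.csv"))
message("Simulated ", nrow(strata), " survey strata from ",
        length(unique(strata$survey_id)), " surveys")

aux <- simulate_aux_tables(world)
write_aux_tables(aux, data_path("population.csv"),
                 data_path("prevalence.csv"))

# cross-sections for the re-screening rate-ratio model, one pooled
# Western/Central/Eastern group and one Southern group, at the region-level
# true rate ratios of the world configuration
rr_cty <- list("Western/Central/Eastern Africa" = c("GHA", "KEN", "TZA"),
               "Southern Africa" = c("ZAF", "ZWE"))
rr_strata <- do.call(rbind, lapply(names(rr_cty), function(g) {
  do.call(rbind, lapply(seq_along(rr_cty[[g]]), function(s) {
    h <- simulate_histories(cfg$rate_ratio$r1, world$config$rr[[g]],
                            cfg$rate_ratio$n_women, 16,
                            seed = cfg$seed + 100L * match(g, names(rr_cty))
                            + s)
    cross_section_histories(h, cfg$rate_ratio$ages[1]:cfg$rate_ratio$ages[2],
                            survey_id = paste0(substr(g, 1, 1), s),
                            country = rr_cty[[g]][s], year = 2015,
                            seed = cfg$seed + 500L + s)
  }))
}))
write_strata(rr_strata, data_path("rate_ratio_strata.csv"))
message("Simulated ", nrow(rr_strata), " single-year-age strata for the ",
        "rate-ratio model (true RR: ",
        paste(names(world$config$rr), round(world$config$rr, 1),
              collapse = "; "), ")")

treatment <- if (isTRUE(cfg$treatment$use_demo)) demo_treatment_data() else
  simulate_treatment(cfg$treatment$config, seed = cfg$seed + 7L)
write_treatment(treatment, data_path("treatment.csv"))

# the world itself is re-derived from (config, seed) downstream, not stored
write_manifest("simulate", cfg, cfg$seed,
               artifacts = c(data_path("strata.csv"),
                             data_path("population.csv"),
                             data_path("prevalence.csv"),
                             data_path("rate_ratio_strata.csv"),
                             data_path("treatment.csv")),
               path = path_of("manifest_simulate.json"))
message("Stage 1 artifacts written under ", data_dir)
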