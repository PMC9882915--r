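# Run configuration and artifact bookkeeping for the analysis scripts: one
# YAML config drives every stage, each stage writes CSV artifacts plus a
# JSON manifest recording the config fingerprint, seed and upstream
# artifacts.

#' Default pipeline run configuration
#'
#' A plain list (YAML-serializable) holding everything the analysis stages
#' need: the synthetic-world settings, MCMC settings, seeds, the reporting
#' aggregates, and sensitivity switches.
#'
#' @param seed base seed; stage seeds are derived as small offsets from it.
#' @param out_dir directory for stage artifacts.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, out_dir = "results") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    mcmc = list(chains = 4, warmup = 2500, iter = 800, thin = 20),
    world = list(),        # overrides to world_config() arguments
    lifetable = list(init = "model", start_age = 30, start_year = 2005,
                     cycles = 15),
    rate_ratio = list(r1 = 0.02, n_women = 12500, n_surveys = 4,
                      ages = c(18, 29)),
    treatment = list(use_demo = TRUE),
    sensitivity = list(year_min = NULL, whs_fixed_effect = FALSE)),
    class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown top-level keys are rejected to catch typos.
#'
#' @param path YAML file.
#' @return `run_config` list merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(cfg)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(cfg[[k]]))
      utils::modifyList(base[[k]], cfg[[k]]) else cfg[[k]]
  }
  structure(base, class = "run_config")
}

# Order-stable fingerprint of an R object (polynomial rolling hash over its
# serialization, mod 2^31 - 1).
config_fingerprint <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 131 + b + 1) %% m
  sprintf("%08x", h)
}

#' Write a stage manifest
#'
#' Records, per pipeline stage, the configuration fingerprint, seed,
#' package version, produced artifacts and the manifests of upstream stages
#' (a reproducibility chain), plus any diagnostics the stage reports.
#'
#' @param stage stage name.
#' @param config the `run_config` used.
#' @param seed the stage seed.
#' @param artifacts character vector of files the stage wrote.
#' @param upstream character vector of upstream manifest paths.
#' @param diagnostics named list (e.g. max Rhat) stored verbatim.
#' @param path output JSON path.
#' @export
write_manifest <- function(stage, config, seed, artifacts,
                           upstream = character(0),
                           diagnostics = list(), path) {
  upstream_fp <- vapply(upstream, function(p) {
    if (file.exists(p)) config_fingerprint(readLines(p, warn = FALSE))
    else NA_character_
  }, character(1L))
  manifest <- list(
    stage = stage,
    config_fingerprint = config_fingerprint(unclass(config)),
    seed = seed,
    package_version = as.character(utils::packageVersion("ccscreen")),
    artifacts = as.list(artifacts),
    upstream = as.list(setNames(upstream_fp, upstream)),
    diagnostics = diagnostics,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Standard prediction grid for the fitted model
#'
#' The full (country, year, age band, serostatus, recall) grid the
#' post-processing stages consume.
#'
#' @param countries ISO3 codes.
#' @param years calendar years.
#' @return data frame grid.
#' @export
prediction_grid <- function(countries, years = 2000:2020) {
  expand.grid(country = countries, year = years,
              age_group = AGE_BANDS_5Y, hiv = c("pos", "neg"),
              recall = c("lifetime", "past3y"), stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}
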