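# Shared setup for the analysis scripts: load the package, read the run
# configuration (first command-line argument, default analysis/config.yaml)
# and create the output directories.

suppressPackageStartupMessages(library(ccscreen))

args <- commandArgs(trailingOnly = TRUE)
cfg_path <- if (length(args) >= 1) args[[1]] else "analysis/config.yaml"
cfg <- if (file.exists(cfg_path)) read_run_config(cfg_path) else
  default_run_config()
data_dir <- file.path(cfg$out_dir, "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

stage_mcmc <- function(seed_offset = 0L)
  mcmc_config(chains = cfg$mcmc$chains, warmup = cfg$mcmc$warmup,
              iter = cfg$mcmc$iter, thin = cfg$mcmc$thin,
              seed = cfg$seed + seed_offset)

path_of <- function(...) file.path(cfg$out_dir, ...)
data_path <- function(...) file.path(data_dir, ...)
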