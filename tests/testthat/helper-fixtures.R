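# Shared fixtures: everything is generated in code at test time.

# A small strata table with valid rows, built by hand.
tiny_strata <- function() {
  data.frame(
    survey_id = c("GHA-2010", "GHA-2010", "KEN-2015"),
    country = c("GHA", "GHA", "KEN"),
    region = c("Western/Central Africa", "Western/Central Africa",
               "Eastern Africa"),
    survey_type = c("DHS", "DHS", "PHIA"),
    year = c(2010.5, 2010.5, 2015),
    age_group = c("25-29", "30-34", "25-29"),
    recall = c("lifetime", "lifetime", "past3y"),
    hiv = c("neg", "neg", "pos"),
    k_eff = c(123.456789012, 80.1, 40),
    n_eff = c(1000.987654321, 900.25, 400),
    stringsAsFactors = FALSE)
}

# Degenerate world: no heterogeneity, handy for exact checks.
flat_world <- function(beta0 = 0, beta_year = 0, beta_recall = 0,
                       gamma = 0, prevalence = 0) {
  cfg <- world_config(
    beta0 = beta0, beta_year = beta_year,
    alpha_age = c("25-29" = 0, "30-34" = 0, "35-39" = 0, "40-44" = 0,
                  "45-49" = 0),
    beta_recall = beta_recall, gamma = gamma,
    sd = list(survey = 0, country = 0, region = 0, slope_country = 0,
              slope_region = 0, hiv_country = 0, hiv_region = 0),
    prevalence = c("Western/Central Africa" = prevalence,
                   "Eastern Africa" = prevalence,
                   "Southern Africa" = prevalence))
  make_world(cfg, seed = 1)
}

# Hand-built trend posterior with D identical (or caller-supplied) draws,
# for testing the deterministic transforms without MCMC.
fake_trend_posterior <- function(D = 4, overrides = list()) {
  countries <- data.frame(country = c("GHA", "KEN"),
                          region = c("Western/Central Africa",
                                     "Eastern Africa"),
                          stringsAsFactors = FALSE)
  regions <- sort(unique(countries$region))
  ages <- c("25-29", "30-34", "35-39", "40-44", "45-49")
  par_names <- c("b0", "b_year", "b_recall", "gam",
                 paste0("alpha[", 1:5, "]"),
                 "sig_s", "sig_c", "sig_r", "tau_c", "tau_r", "om_c",
                 "om_r",
                 paste0("a_c[", 1:2, "]"), paste0("a_r[", 1:2, "]"),
                 paste0("v_c[", 1:2, "]"), paste0("v_r[", 1:2, "]"),
                 paste0("g_c[", 1:2, "]"), paste0("g_r[", 1:2, "]"))
  draws <- matrix(0, D, length(par_names),
                  dimnames = list(NULL, par_names))
  draws[, c("sig_s", "sig_c", "sig_r", "tau_c", "tau_r", "om_c",
            "om_r")] <- 1e-12
  for (nm in names(overrides)) draws[, nm] <- overrides[[nm]]
  structure(list(draws = draws, rhat = setNames(rep(1, ncol(draws)),
                                                par_names),
                 surveys = data.frame(), countries = countries,
                 regions = regions, ages = ages,
                 whs_effect = FALSE, converged = TRUE),
            class = "trend_posterior")
}

# Default-scale synthetic dataset + fit, computed once per test run and
# cached (several test files reuse it).
shared_fit_cache <- new.env(parent = emptyenv())
shared_trend_fit <- function() {
  if (is.null(shared_fit_cache$fit)) {
    w <- make_world(seed = 42)
    strata <- simulate_surveys(w, default_survey_design(w), seed = 43)
    aux <- simulate_aux_tables(w)
    fit <- suppressWarnings(fit_trend_model(
      strata, aux,
      mcmc_config(chains = 4, warmup = 2500, iter = 800, thin = 20,
                  seed = 7)))
    shared_fit_cache$world <- w
    shared_fit_cache$strata <- strata
    shared_fit_cache$aux <- aux
    shared_fit_cache$fit <- fit
  }
  list(world = shared_fit_cache$world, strata = shared_fit_cache$strata,
       aux = shared_fit_cache$aux, fit = shared_fit_cache$fit)
}

# Cross-sectioned rate-ratio inputs from histories with known truth.
make_rate_ratio_inputs <- function(rr, seed = 1, r1 = 0.02, n = 12500,
                                   surveys = 4) {
  ctys <- rep(c("KEN", "TZA", "GHA", "NGA", "ZMB", "UGA"),
              length.out = surveys)
  strata <- do.call(rbind, lapply(seq_len(surveys), function(s) {
    h <- simulate_histories(r1, rr, n, 16, seed = seed * 10 + s,
                            start_age = 15)
    cross_section_histories(h, 18:29, survey_id = paste0("S", s),
                            country = ctys[s], year = 2015,
                            seed = seed * 100 + s)
  }))
  build_rate_ratio_inputs(strata)
}

quick_mcmc <- function(seed = 1)
  mcmc_config(chains = 2, warmup = 500, iter = 500, seed = seed)
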