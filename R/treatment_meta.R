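# Bayesian random-effects meta-analysis of cervical pre-cancer treatment
# coverage among women with an abnormal, non-cancer screening result.

treatment_model_string <- function(sigma_fixed = NULL) {
  sigma_line <- if (is.null(sigma_fixed))
    "  sigma ~ dnorm(0, 1) T(0,)" else
      sprintf("  sigma <- %.12g", sigma_fixed)
  paste0("model {
  for (i in 1:C) {
    k[i] ~ dbin(p[i], n[i])
    logit(p[i]) <- mu + u[i]
    u[i] ~ dnorm(0, pow(sigma + 1.0E-12, -2))
  }
  mu ~ dnorm(0, 0.16)
", sigma_line, "
}")
}

#' Fit the treatment-coverage meta-analysis
#'
#' Logistic random-effects model for country-level treated/abnormal counts:
#' \eqn{k_c \sim Binomial(n_c, expit(\mu + u_c))},
#' \eqn{u_c \sim N(0, \sigma^2)}, with priors \eqn{\mu \sim N(0, 2.5^2)} and
#' \eqn{\sigma \sim} half-N(0, 1).
#'
#' @param observations data frame `country, k_treated, n_abnormal` (see
#'   [load_treatment()]).
#' @param mcmc an [mcmc_config()].
#' @param sigma_fixed optionally pin the between-country SD (e.g. `0` for a
#'   common-proportion model; used by calibration checks).
#' @return object of class `treatment_posterior`: `draws` (columns `mu`,
#'   `sigma`, `u[i]`, `p[i]`), `countries`, `rhat`, `converged`.
#' @export
fit_treatment_meta <- function(observations, mcmc = mcmc_config(),
                               sigma_fixed = NULL) {
  if (!nrow(observations)) stop("empty observation set", call. = FALSE)
  # sort by country so row order never affects the sampler's node order
  observations <- observations[order(observations$country), , drop = FALSE]
  stopifnot(all(observations$k_treated >= 0),
            all(observations$k_treated <= observations$n_abnormal),
            all(observations$n_abnormal >= 1))
  dat <- list(C = nrow(observations),
              k = as.integer(round(observations$k_treated)),
              n = as.integer(round(observations$n_abnormal)))
  monitor <- c("mu", "sigma", "u", "p")
  fit <- run_jags(treatment_model_string(sigma_fixed), dat, monitor, mcmc)
  converged <- !warn_if_unconverged(fit$rhat, "treatment meta-analysis")
  structure(list(draws = fit$draws, rhat = fit$rhat,
                 countries = observations$country, converged = converged),
            class = "treatment_posterior")
}

#' @export
print.treatment_posterior <- function(x, ...) {
  cat("Treatment meta-analysis posterior,", length(x$countries),
      "countries\n")
  print(pooled_estimate(x))
  invisible(x)
}

#' Pooled treatment coverage
#'
#' The pooled summary is the typical-country proportion \eqn{expit(\mu)}
#' (default), or the population-average proportion
#' \eqn{E[expit(\mu + u)], u \sim N(0, \sigma^2)} computed by Monte Carlo
#' over the posterior draws.
#'
#' @param posterior a [fit_treatment_meta()] object.
#' @param type `"typical"` (default) or `"population"`.
#' @param seed RNG seed for the population-average Monte Carlo.
#' @return data frame `unit, median, lo95, hi95`.
#' @export
pooled_estimate <- function(posterior, type = c("typical", "population"),
                            seed = 1) {
  type <- match.arg(type)
  mu <- posterior$draws[, "mu"]
  if (type == "typical") {
    p <- expit(mu)
  } else {
    set.seed(seed)
    p <- expit(mu + rnorm(length(mu), 0, posterior$draws[, "sigma"]))
  }
  data.frame(unit = paste0("pooled (", type, ")"),
             median = median(p),
             lo95 = unname(quantile(p, 0.025)),
             hi95 = unname(quantile(p, 0.975)))
}

#' Per-country treatment coverage estimates
#'
#' Posterior medians and 95% credible intervals of
#' \eqn{expit(\mu + u_c)} per country.
#'
#' @param posterior a [fit_treatment_meta()] object.
#' @return data frame `unit, median, lo95, hi95`, one row per country.
#' @export
country_estimates <- function(posterior) {
  C <- length(posterior$countries)
  p <- jags_cols(posterior$draws, "p", C)
  qs <- t(apply(p, 2, quantile, c(0.5, 0.025, 0.975)))
  data.frame(unit = posterior$countries, median = qs[, 1L],
             lo95 = qs[, 2L], hi95 = qs[, 3L], row.names = NULL)
}

#' Packaged demo treatment dataset (synthetic counts)
#'
#' Four-country demonstration table with per-country proportions matching
#' published magnitudes for sub-Saharan Africa (Malawi 77%, Cape Verde 82%,
#' Tanzania 90%, Zambia 90%) but synthetic denominators: the real surveys'
#' per-country denominators (113 women in total) are not public, so counts
#' here are constructed, not observed.
#'
#' @return data frame `country, k_treated, n_abnormal`.
#' @export
demo_treatment_data <- function() {
  n <- c(MWI = 35, CPV = 17, TZA = 31, ZMB = 30)
  p <- c(MWI = 0.77, CPV = 0.82, TZA = 0.90, ZMB = 0.90)
  data.frame(country = names(n),
             k_treated = as.integer(round(n * p)),
             n_abnormal = as.integer(n),
             stringsAsFactors = FALSE)
}
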