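# Four-level Bayesian multilevel binomial logistic regression of lifetime
# and past 3-year screening coverage, with hierarchical HIV slopes and
# prevalence-weighted marginalization for serostatus-unreported strata.
#
# Linear predictor (logit scale), for stratum i in survey s, country c,
# region r:
#   eta = b0 + u_r + u_c + u_s + alpha_age
#         + (b_year + v_r + v_c) * (year - 2010)/10
#         + b_recall * 1[recall = past3y]  (+ b_whs * 1[type = WHS])
#   logit p_neg = eta ;  logit p_pos = eta + (gamma + g_r + g_c)
#   hiv = "all":  p = pi * p_pos + (1 - pi) * p_neg
#
# The hierarchy is parameterized in its hierarchically-centered form, the
# efficient choice for Gibbs/slice updates of nested data-rich levels:
# absolute effects a_s ~ N(a_c, sig_s^2), a_c ~ N(a_r, sig_c^2),
# a_r ~ N(b0, sig_r^2), and likewise for the year slopes (v_c ~ N(v_r,.),
# v_r ~ N(b_year,.)) and the HIV slopes (g_c ~ N(g_r,.), g_r ~ N(gam,.)).
# Deviations u_* are recovered by differencing after sampling. All SDs have
# half-Normal(0,1) priors and fixed effects Normal(0, 2.5^2); the recall
# offset is truncated <= 0 so a past 3-year report can never exceed a
# lifetime report.

trend_model_string <- function(n_ages, whs = FALSE) {
  whs_term <- if (whs) " + b_whs * whs[i]" else ""
  whs_prior <- if (whs) "  b_whs ~ dnorm(0, 0.16)\n" else ""
  alpha_prior <- if (n_ages > 1)
    "  for (a in 2:A) { alpha[a] ~ dnorm(0, 0.16) }\n" else ""
  paste0("model {
  for (i in 1:N) {
    eta[i] <- a_s[srv[i]] + alpha[age[i]]
              + b_recall * rec[i]", whs_term, "
    pneg[i] <- ilogit(eta[i])
    ppos[i] <- ilogit(eta[i] + g_c[cty[i]])
    p[i] <- wpos[i] * ppos[i] + (1 - wpos[i]) * pneg[i]
    k[i] ~ dbin(p[i], n[i])
  }
  alpha[1] <- 0
", alpha_prior, "  b0 ~ dnorm(0, 0.16)
  b_year ~ dnorm(0, 0.16)
  b_recall ~ dnorm(0, 0.16) T(,0)
  gam ~ dnorm(0, 0.16)
", whs_prior, "  for (s in 1:S) {
    a_s[s] ~ dnorm(a_c[scty[s]] + v_c[scty[s]] * ts[s], pow(sig_s, -2))
  }
  for (c in 1:C) {
    a_c[c] ~ dnorm(a_r[creg[c]], pow(sig_c, -2))
    v_c[c] ~ dnorm(v_r[creg[c]], pow(tau_c, -2))
    g_c[c] ~ dnorm(g_r[creg[c]], pow(om_c, -2))
  }
  for (r in 1:R) {
    a_r[r] ~ dnorm(b0, pow(sig_r, -2))
    v_r[r] ~ dnorm(b_year, pow(tau_r, -2))
    g_r[r] ~ dnorm(gam, pow(om_r, -2))
  }
  sig_s ~ dnorm(0, 1) T(0,)
  sig_c ~ dnorm(0, 1) T(0,)
  sig_r ~ dnorm(0, 1) T(0,)
  tau_c ~ dnorm(0, 1) T(0,)
  tau_r ~ dnorm(0, 1) T(0,)
  om_c ~ dnorm(0, 1) T(0,)
  om_r ~ dnorm(0, 1) T(0,)
}")
}

# Index the strata against nested survey/country/region levels and resolve
# mixture weights; shared by the fitter and the posterior predictive check.
prepare_trend_data <- function(strata, aux, year_min = NULL,
                               whs_effect = FALSE) {
  validate_strata(strata, aux = aux)
  strata <- strata[strata$recall %in% c("lifetime", "past3y"), ]
  if (!is.null(year_min)) strata <- strata[strata$year >= year_min, ]
  if (!nrow(strata)) stop("empty observation set", call. = FALSE)
  cnt <- integerize_counts(strata$k_eff, strata$n_eff)
  keep <- round(strata$n_eff) >= 1  # zero-information strata carry no data
  strata <- strata[keep, , drop = FALSE]
  k <- cnt$k[keep]; n <- cnt$n[keep]
  surveys <- unique(strata[c("survey_id", "country", "region", "year")])
  rownames(surveys) <- NULL
  countries <- unique(surveys[c("country", "region")])
  countries <- countries[order(countries$country), ]
  rownames(countries) <- NULL
  regions <- sort(unique(countries$region))
  ages <- AGE_BANDS_5Y[AGE_BANDS_5Y %in% strata$age_group]
  if (!all(strata$age_group %in% ages))
    stop("trend model expects 5-year age bands", call. = FALSE)
  wpos <- ifelse(strata$hiv == "pos", 1, 0)
  for (i in which(strata$hiv == "all"))
    wpos[i] <- aux_prevalence(aux, strata$country[i], strata$year[i],
                              strata$age_group[i])
  dat <- list(
    N = nrow(strata), k = k, n = n,
    rec = as.numeric(strata$recall == "past3y"),
    wpos = wpos,
    age = match(strata$age_group, ages),
    srv = match(strata$survey_id, surveys$survey_id),
    cty = match(strata$country, countries$country),
    reg = match(strata$region, regions),
    A = length(ages), S = nrow(surveys), C = nrow(countries),
    R = length(regions),
    scty = match(surveys$country, countries$country),
    creg = match(countries$region, regions),
    ts = (surveys$year - 2010) / 10)
  if (whs_effect) dat$whs <- as.numeric(strata$survey_type == "WHS")
  if (any(!is.finite(unlist(dat[c("ts", "rec", "wpos")]))))
    stop("non-finite design inputs", call. = FALSE)
  list(jags = dat, strata = strata, surveys = surveys,
       countries = countries, regions = regions, ages = ages)
}

#' Fit the screening coverage trend model
#'
#' Fits the four-level (survey, country, region, sub-Saharan Africa)
#' multilevel binomial logistic regression jointly to lifetime and past
#' 3-year strata. Serostatus-unreported strata (`hiv = "all"`) enter through
#' the prevalence-weighted mixture likelihood; effective counts are
#' integerized per [integerize_counts()]. Sampling uses JAGS with explicit
#' per-chain seeds.
#'
#' @param strata validated strata data frame (lifetime / past3y rows;
#'   `past1y` rows are ignored by this model).
#' @param aux [aux_tables()] object resolving prevalence for `hiv = "all"`
#'   rows.
#' @param mcmc an [mcmc_config()].
#' @param year_min optional sensitivity restriction, e.g. `2010` to use only
#'   surveys from 2010 onwards.
#' @param whs_effect include a fixed effect for WHS surveys (sensitivity
#'   analysis).
#' @return object of class `trend_posterior` with elements `draws` (matrix,
#'   draws x parameters), `rhat`, the index tables (`surveys`, `countries`,
#'   `regions`, `ages`), the prepared data, and a `converged` flag. Warns and
#'   flags (but still returns) if any split-\eqn{\hat{R}} exceeds 1.05.
#' @export
fit_trend_model <- function(strata, aux, mcmc = mcmc_config(),
                            year_min = NULL, whs_effect = FALSE) {
  prep <- prepare_trend_data(strata, aux, year_min = year_min,
                             whs_effect = whs_effect)
  monitor <- c("b0", "b_year", "b_recall", "gam", "alpha",
               "sig_s", "sig_c", "sig_r", "tau_c", "tau_r", "om_c", "om_r",
               "a_s", "a_c", "a_r", "v_c", "v_r", "g_c", "g_r",
               if (whs_effect) "b_whs")
  fit <- run_jags(trend_model_string(prep$jags$A, whs = whs_effect),
                  prep$jags, monitor, mcmc)
  converged <- !warn_if_unconverged(fit$rhat, "trend model")
  structure(list(draws = fit$draws, sims = fit$sims, rhat = fit$rhat,
                 surveys = prep$surveys, countries = prep$countries,
                 regions = prep$regions, ages = prep$ages,
                 data = prep, mcmc = mcmc, whs_effect = whs_effect,
                 converged = converged),
            class = "trend_posterior")
}

#' @export
print.trend_posterior <- function(x, ...) {
  cat("Trend model posterior:", nrow(x$draws), "draws,",
      x$data$jags$N, "strata,", x$data$jags$S, "surveys,",
      x$data$jags$C, "countries,", x$data$jags$R, "regions\n")
  cat("  max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  fx <- x$draws[, c("b0", "b_year", "b_recall", "gam")]
  print(round(t(apply(fx, 2, quantile, c(0.025, 0.5, 0.975))), 3))
  invisible(x)
}

# Parameter matrices keyed by the posterior's index tables.
trend_param <- function(posterior, name, n = 1L)
  jags_cols(posterior$draws, name, n)

#' Success probability of one stratum under one parameter draw
#'
#' Evaluates the model's stratum-level success probability for a single
#' parameter draw: the serostatus-specific probabilities are logistic in the
#' linear predictor, and a serostatus-mixed stratum (`hiv = "all"`) has the
#' prevalence-weighted mixture probability
#' \eqn{\pi p_{pos} + (1 - \pi) p_{neg}}.
#'
#' @param params list of parameter values for one draw: `beta0`, `u_region`,
#'   `u_country`, `u_survey`, `alpha_age` (named by band), `beta_year`,
#'   `v_region`, `v_country`, `beta_recall`, `gamma`, `g_region`,
#'   `g_country`, optionally `beta_whs`. Missing components default to 0.
#' @param covariates list with `year`, `age_group`, `recall` (`"lifetime"`
#'   or `"past3y"`), `hiv` (`"pos"`, `"neg"`, `"all"`), optionally `whs`
#'   (logical).
#' @param prevalence HIV prevalence \eqn{\pi}; required when
#'   `covariates$hiv == "all"`.
#' @return success probability in (0, 1).
#' @export
stratum_probability <- function(params, covariates, prevalence = NULL) {
  g0 <- function(x) if (is.null(x)) 0 else x
  alpha <- if (is.null(params$alpha_age)) 0 else {
    if (!covariates$age_group %in% names(params$alpha_age))
      stop("age_group '", covariates$age_group, "' not in params$alpha_age")
    params$alpha_age[[covariates$age_group]]
  }
  eta <- g0(params$beta0) + g0(params$u_region) + g0(params$u_country) +
    g0(params$u_survey) + alpha +
    (g0(params$beta_year) + g0(params$v_region) + g0(params$v_country)) *
      (covariates$year - 2010) / 10 +
    g0(params$beta_recall) * (covariates$recall == "past3y") +
    g0(params$beta_whs) * isTRUE(covariates$whs)
  hiv_lor <- g0(params$gamma) + g0(params$g_region) + g0(params$g_country)
  p_neg <- expit(eta)
  p_pos <- expit(eta + hiv_lor)
  switch(covariates$hiv,
         neg = p_neg,
         pos = p_pos,
         all = {
           if (is.null(prevalence))
             stop("hiv='all' requires a prevalence", call. = FALSE)
           prevalence * p_pos + (1 - prevalence) * p_neg
         },
         stop("unknown hiv label: ", covariates$hiv))
}

#' Posterior coverage draws on a prediction grid
#'
#' Deterministic per-draw transform of the fitted parameters onto a grid of
#' (country, year, age band, serostatus, recall) cells. Predictions are at
#' the survey-level mean (`u_survey = 0`). Countries must have been observed
#' in the fit; use [impute_country()] for countries without surveys.
#'
#' @param posterior a [fit_trend_model()] object.
#' @param grid data frame with columns `country, year, age_group, hiv, recall`
#'   (`hiv` in pos/neg, `recall` in lifetime/past3y).
#' @return object of class `coverage_draws`: list with `grid` and `draws`
#'   (matrix, draws x grid rows), values strictly in (0, 1).
#' @export
predict_coverage <- function(posterior, grid) {
  stopifnot(all(c("country", "year", "age_group", "hiv", "recall") %in%
                  names(grid)),
            all(grid$hiv %in% c("pos", "neg")),
            all(grid$recall %in% c("lifetime", "past3y")))
  ctab <- posterior$countries
  ci <- match(grid$country, ctab$country)
  if (anyNA(ci))
    stop("countries not in the fitted model (impute instead): ",
         paste(unique(grid$country[is.na(ci)]), collapse = ", "),
         call. = FALSE)
  ai <- match(grid$age_group, posterior$ages)
  if (anyNA(ai)) stop("age_group outside the fitted bands", call. = FALSE)
  d <- posterior$draws
  C <- nrow(ctab); A <- length(posterior$ages)
  br <- d[, "b_recall"]
  alpha <- trend_param(posterior, "alpha", A)
  a_c <- trend_param(posterior, "a_c", C)
  v_c <- trend_param(posterior, "v_c", C)
  g_c <- trend_param(posterior, "g_c", C)
  draws <- matrix(NA_real_, nrow(d), nrow(grid))
  for (j in seq_len(nrow(grid))) {
    tt <- (grid$year[j] - 2010) / 10
    eta <- a_c[, ci[j]] + alpha[, ai[j]] + v_c[, ci[j]] * tt +
      br * (grid$recall[j] == "past3y") +
      g_c[, ci[j]] * (grid$hiv[j] == "pos")
    draws[, j] <- expit(eta)
  }
  structure(list(grid = grid, draws = draws), class = "coverage_draws")
}

#' @export
print.coverage_draws <- function(x, ...) {
  cat("Coverage draws:", ncol(x$draws), "grid cells x", nrow(x$draws),
      "draws\n")
  invisible(x)
}

#' Summarize coverage draws
#'
#' @param object a `coverage_draws` object.
#' @param ... unused.
#' @return the grid with posterior `median`, `lo95`, `hi95` columns.
#' @export
summary.coverage_draws <- function(object, ...) {
  qs <- t(apply(object$draws, 2L, quantile, c(0.025, 0.5, 0.975)))
  cbind(object$grid,
        data.frame(median = qs[, 2L], lo95 = qs[, 1L], hi95 = qs[, 3L]))
}

#' Adjusted HIV odds ratio draws
#'
#' Screening odds ratio for women living with HIV versus women without HIV,
#' adjusted for age, time and recall period:
#' \eqn{\exp(\gamma + g_r + g_c)} per draw at country level,
#' \eqn{\exp(\gamma + g_r)} at region level, \eqn{\exp(\gamma)} overall.
#'
#' @param posterior a [fit_trend_model()] object.
#' @param country optional ISO3 code of a fitted country.
#' @param region optional region label (used when `country` is `NULL`).
#' @return list with `draws` (numeric vector of OR draws) and `summary`
#'   (median and 95% credible interval).
#' @export
hiv_odds_ratio <- function(posterior, country = NULL, region = NULL) {
  d <- posterior$draws
  if (!is.null(country)) {
    ci <- match(country, posterior$countries$country)
    if (is.na(ci)) stop("country not in the fitted model: ", country)
    lor <- trend_param(posterior, "g_c", nrow(posterior$countries))[, ci]
  } else if (!is.null(region)) {
    ri <- match(region, posterior$regions)
    if (is.na(ri)) stop("region not in the fitted model: ", region)
    lor <- trend_param(posterior, "g_r", length(posterior$regions))[, ri]
  } else {
    lor <- d[, "gam"]
  }
  or <- exp(lor)
  list(draws = or,
       summary = data.frame(
         median = median(or),
         lo95 = unname(quantile(or, 0.025)),
         hi95 = unname(quantile(or, 0.975))))
}

#' Posterior predictive check of the fitted trend model
#'
#' For every stratum used in the fit, replicated counts
#' \eqn{k^{rep} \sim Binomial(n, p^{(d)})} are simulated across posterior
#' draws (with the stratum's own survey effect, i.e. in-sample) and compared
#' with the observed count: the report gives each stratum's central 95%
#' predictive interval, whether the observation falls inside, and its
#' standardized residual \eqn{(k - \bar{k}^{rep}) / sd(k^{rep})}.
#'
#' @param posterior a [fit_trend_model()] object.
#' @param seed RNG seed for the replicate draws.
#' @return list with `strata` (per-stratum report) and `prop_inside`
#'   (fraction of strata inside their central 95% predictive interval).
#' @export
posterior_predictive_check <- function(posterior, seed = 1) {
  set.seed(seed)
  dat <- posterior$data$jags
  p <- stratum_p_draws(posterior)  # draws x strata, includes u_s
  D <- nrow(p)
  rep_int <- matrix(NA_real_, ncol(p), 4L)
  for (i in seq_len(ncol(p))) {
    krep <- rbinom(D, dat$n[i], p[, i])
    rep_int[i, ] <- c(quantile(krep, c(0.025, 0.975)), mean(krep), sd(krep))
  }
  obs <- dat$k
  inside <- obs >= rep_int[, 1L] & obs <= rep_int[, 2L]
  z <- (obs - rep_int[, 3L]) / pmax(rep_int[, 4L], 1e-9)
  report <- cbind(posterior$data$strata,
                  data.frame(k = obs, n = dat$n,
                             lo95 = rep_int[, 1L], hi95 = rep_int[, 2L],
                             inside = inside, z = z))
  list(strata = report, prop_inside = mean(inside))
}

# Per-stratum success probability draws for the fitted data (in-sample,
# including survey effects and mixture weights).
stratum_p_draws <- function(posterior) {
  dat <- posterior$data$jags
  d <- posterior$draws
  alpha <- trend_param(posterior, "alpha", dat$A)
  a_s <- trend_param(posterior, "a_s", dat$S)  # includes the survey-year slope
  g_c <- trend_param(posterior, "g_c", dat$C)
  bwhs <- if (posterior$whs_effect) d[, "b_whs"] else 0
  whs <- if (posterior$whs_effect) dat$whs else rep(0, dat$N)
  p <- matrix(NA_real_, nrow(d), dat$N)
  for (i in seq_len(dat$N)) {
    eta <- a_s[, dat$srv[i]] + alpha[, dat$age[i]] +
      d[, "b_recall"] * dat$rec[i] + bwhs * whs[i]
    pneg <- expit(eta)
    ppos <- expit(eta + g_c[, dat$cty[i]])
    p[, i] <- dat$wpos[i] * ppos + (1 - dat$wpos[i]) * pneg
  }
  p
}

#' Persist posterior draws as long-format CSV
#'
#' @param posterior a `trend_posterior`.
#' @param path output CSV `draw, parameter, value`.
#' @export
write_posterior <- function(posterior, path) {
  d <- posterior$draws
  long <- data.frame(draw = rep(seq_len(nrow(d)), ncol(d)),
                     parameter = rep(colnames(d), each = nrow(d)),
                     value = as.vector(d))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Persist coverage draws as long-format CSV
#'
#' @param coverage a `coverage_draws` object.
#' @param path output CSV `country, year, age_group, hiv, recall, draw, p`.
#' @export
write_coverage_draws <- function(coverage, path) {
  g <- coverage$grid
  D <- nrow(coverage$draws)
  long <- g[rep(seq_len(nrow(g)), each = D), , drop = FALSE]
  long$draw <- rep(seq_len(D), nrow(g))
  long$p <- as.vector(coverage$draws)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
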