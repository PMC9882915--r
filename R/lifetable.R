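# Re-screening analysis: rate-ratio identification from cross-sectional
# age increments, conversion of past 3-year coverage into first- and
# re-screening rates, and a never/once/twice+ multistate life table for a
# cohort aged 30 in 2005 followed to age 45 in 2020.

#' Paired age-increment records for rate-ratio estimation
#'
#' From single-year-age strata (lifetime and past-year recall), builds one
#' record per (survey, age a) combining the lifetime coverage at ages a and
#' a+1 with the past-year screening fraction at a, restricted to ages 18-29
#' where cohort/period biases are smallest. Each record also carries the
#' crude moment estimate of the rate ratio: with
#' \eqn{q_1 = \Delta L / (1 - L(a))} the first-screening probability implied
#' by the lifetime increment and
#' \eqn{q_{re} = (P_{1y} - \Delta L) / L(a)} the re-screening probability
#' among the previously screened,
#' \eqn{\widehat{RR} = \log(1 - q_{re}) / \log(1 - q_1)}. Records with a
#' negative increment or \eqn{P_{1y} < \Delta L} are flagged (`ok = FALSE`)
#' and excluded from the crude estimator but retained for the Bayesian fit,
#' which models the sampling noise that produces them.
#'
#' @param observations strata data frame containing single-year `age_group`
#'   rows with recall `"lifetime"` and `"past1y"`.
#' @param age_range inclusive age window (default 18-29).
#' @return data frame: `survey_id, country, region, age, L_a, L_a1, P1y,
#'   n_L, n_L1, n_P, k_L, k_L1, k_P, q1, qre, rr_crude, ok`.
#' @export
build_rate_ratio_inputs <- function(observations, age_range = c(18, 29)) {
  obs <- observations[observations$age_group %in% as.character(15:49), ]
  obs$age <- as.integer(obs$age_group)
  obs <- obs[obs$age >= age_range[1L] & obs$age <= age_range[2L] + 1L, ]
  life <- obs[obs$recall == "lifetime", ]
  past <- obs[obs$recall == "past1y", ]
  if (!nrow(life) || !nrow(past))
    stop("need single-year-age lifetime and past1y strata", call. = FALSE)
  out <- list()
  for (sid in unique(life$survey_id)) {
    ls <- life[life$survey_id == sid, ]
    ps <- past[past$survey_id == sid, ]
    for (a in age_range[1L]:age_range[2L]) {
      i0 <- which(ls$age == a); i1 <- which(ls$age == a + 1L)
      ip <- which(ps$age == a)
      if (!length(i0) || !length(i1) || !length(ip)) next
      L_a <- ls$k_eff[i0] / ls$n_eff[i0]
      L_a1 <- ls$k_eff[i1] / ls$n_eff[i1]
      P1y <- ps$k_eff[ip] / ps$n_eff[ip]
      dL <- L_a1 - L_a
      q1 <- if (L_a < 1) dL / (1 - L_a) else NA_real_
      qre <- if (L_a > 0) (P1y - dL) / L_a else NA_real_
      ok <- is.finite(q1) && is.finite(qre) && dL >= 0 && P1y >= dL &&
        q1 < 1 && qre < 1
      rr_crude <- if (ok && q1 > 0) log(1 - qre) / log(1 - q1) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        survey_id = sid, country = ls$country[i0], region = ls$region[i0],
        age = a, L_a = L_a, L_a1 = L_a1, P1y = P1y,
        n_L = ls$n_eff[i0], n_L1 = ls$n_eff[i1], n_P = ps$n_eff[ip],
        k_L = ls$k_eff[i0], k_L1 = ls$k_eff[i1], k_P = ps$k_eff[ip],
        q1 = q1, qre = qre, rr_crude = rr_crude, ok = ok,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    stop("no paired (age, age+1, past-year) records in the inputs",
         call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Region grouping for rate ratios: Western/Central and Eastern Africa are
# pooled; Southern Africa stands alone.
rate_ratio_group <- function(region) {
  ifelse(region == "Southern Africa", "Southern Africa",
         "Western/Central/Eastern Africa")
}

rate_ratio_model_string <- "model {
  for (s in 1:S) {
    L[s, 1] ~ dbeta(1, 1)
    log_r1[s] ~ dnorm(mu_r1, pow(sd_r1, -2))
    r1[s] <- exp(log_r1[s])
    for (a in 1:(A - 1)) {
      L[s, a + 1] <- L[s, a] + (1 - L[s, a]) * (1 - exp(-r1[s]))
    }
  }
  for (i in 1:N) {
    kL[i] ~ dbin(L[srv[i], aidx[i]], nL[i])
  }
  for (j in 1:M) {
    p1y[j] <- (1 - L[psrv[j], paidx[j]]) * (1 - exp(-r1[psrv[j]])) +
              L[psrv[j], paidx[j]] * (1 - exp(-RR[grp[psrv[j]]] * r1[psrv[j]]))
    kP[j] ~ dbin(p1y[j], nP[j])
  }
  for (g in 1:G) {
    log_RR[g] ~ dnorm(0, 0.25)
    RR[g] <- exp(log_RR[g])
  }
  mu_r1 ~ dnorm(-3, 0.25)
  sd_r1 ~ dnorm(0, 1) T(0,)
}"

#' Fit the re-screening rate-ratio model
#'
#' Hierarchical binomial model relating lifetime-coverage increments between
#' successive single-year ages to past-year screening fractions. Per survey
#' \eqn{s}, a stationary first-screening rate \eqn{r_1^{(s)}} (survey-level
#' random effect on the log scale) drives the lifetime recursion
#' \eqn{L(a+1) = L(a) + (1 - L(a))(1 - e^{-r_1})} from a free baseline
#' \eqn{L(18)}; lifetime counts are binomial in \eqn{L(a)} and past-year
#' counts binomial in
#' \eqn{(1-L(a))(1-e^{-r_1}) + L(a)(1-e^{-RR \cdot r_1})}, where the rate
#' ratio \eqn{RR} is shared within a region group (Western/Central/Eastern
#' pooled; Southern separate). Priors: \eqn{\log RR \sim N(0, 2^2)},
#' \eqn{\log r_1} intercept \eqn{\sim N(-3, 2^2)}, survey SD half-N(0,1).
#'
#' @param inputs [build_rate_ratio_inputs()] output (flagged records are
#'   retained; the binomial likelihood accommodates them).
#' @param mcmc an [mcmc_config()].
#' @return object of class `rate_ratio_posterior`: list with `draws` (matrix
#'   with columns `RR[g]`, `mu_r1`, `sd_r1`, `log_r1[s]`), `groups`,
#'   `surveys`, `rhat`, `converged`.
#' @export
fit_rate_ratio <- function(inputs, mcmc = mcmc_config()) {
  inputs$group <- rate_ratio_group(inputs$region)
  surveys <- unique(inputs[c("survey_id", "group")])
  rownames(surveys) <- NULL
  groups <- sort(unique(surveys$group))
  ages <- sort(unique(c(inputs$age, inputs$age + 1L)))
  A <- length(ages)
  # lifetime cells: age a rows plus the a+1 cell of the oldest record
  life_rows <- unique(rbind(
    data.frame(survey_id = inputs$survey_id, age = inputs$age,
               k = round(inputs$k_L), n = round(inputs$n_L)),
    data.frame(survey_id = inputs$survey_id, age = inputs$age + 1L,
               k = round(inputs$k_L1), n = round(inputs$n_L1))))
  dat <- list(
    S = nrow(surveys), A = A, G = length(groups),
    N = nrow(life_rows),
    kL = life_rows$k, nL = life_rows$n,
    srv = match(life_rows$survey_id, surveys$survey_id),
    aidx = match(life_rows$age, ages),
    M = nrow(inputs),
    kP = round(inputs$k_P), nP = round(inputs$n_P),
    psrv = match(inputs$survey_id, surveys$survey_id),
    paidx = match(inputs$age, ages),
    grp = match(surveys$group, groups))
  fit <- run_jags(rate_ratio_model_string, dat,
                  c("RR", "log_RR", "mu_r1", "sd_r1", "log_r1"), mcmc)
  converged <- !warn_if_unconverged(fit$rhat, "rate-ratio model")
  missing_groups <- setdiff(unique(rate_ratio_group(REGIONS)), groups)
  if (length(missing_groups))
    warning("no surveys for region group(s): ",
            paste(missing_groups, collapse = ", "), call. = FALSE)
  structure(list(draws = fit$draws, rhat = fit$rhat, groups = groups,
                 surveys = surveys, converged = converged),
            class = "rate_ratio_posterior")
}

#' @export
print.rate_ratio_posterior <- function(x, ...) {
  cat("Rate-ratio posterior (re-screening : first screening):\n")
  rr <- jags_cols(x$draws, "RR", length(x$groups))
  qs <- t(apply(rr, 2, quantile, c(0.025, 0.5, 0.975)))
  rownames(qs) <- x$groups
  print(round(qs, 1))
  invisible(x)
}

#' Rate-ratio draws for a region group
#'
#' @param posterior a `rate_ratio_posterior`.
#' @param group region-group label (`"Western/Central/Eastern Africa"` or
#'   `"Southern Africa"`); a region label is also accepted and mapped.
#' @return numeric vector of RR draws.
#' @export
rate_ratio_draws <- function(posterior, group) {
  if (group %in% REGIONS) group <- rate_ratio_group(group)
  gi <- match(group, posterior$groups)
  if (is.na(gi)) stop("no fitted rate ratio for group: ", group,
                      call. = FALSE)
  jags_cols(posterior$draws, "RR", length(posterior$groups))[, gi]
}

#' Solve screening rates from past 3-year coverage
#'
#' Inverts the window equation linking the past 3-year coverage \eqn{S_3} of
#' a population with never-screened fraction \eqn{S_0} to the first-screening
#' rate: among the never-screened any screen in the 3-year window is a first
#' screen, among the ever-screened window screening occurs at the
#' re-screening rate, so
#' \deqn{S_3 = S_0 (1 - e^{-3 r_1}) + (1 - S_0)(1 - e^{-3 RR r_1}).}
#' The right-hand side is strictly increasing in \eqn{r_1}, and the root is
#' found to \eqn{|\Delta| < 10^{-10}}. An \eqn{S_3} at or above the
#' supremum (1) is clamped, with a flag.
#'
#' @param S3 past 3-year coverage in `[0, 1)`.
#' @param S0 current never-screened fraction in `[0, 1]`.
#' @param RR re-screening : first-screening rate ratio, > 0.
#' @return list `r1`, `r2 = RR * r1`, `clamped`.
#' @export
solve_screening_rates <- function(S3, S0, RR) {
  stopifnot(S0 >= 0, S0 <= 1, RR > 0, S3 >= 0)
  clamped <- FALSE
  if (S3 >= 1) { S3 <- 1 - 1e-12; clamped <- TRUE }
  if (S3 == 0) return(list(r1 = 0, r2 = 0, clamped = FALSE))
  f <- function(r1) S0 * (1 - exp(-3 * r1)) +
    (1 - S0) * (1 - exp(-3 * RR * r1)) - S3
  hi <- 1
  while (f(hi) < 0 && hi < 1e8) hi <- hi * 2
  r1 <- uniroot(f, c(0, hi), tol = 1e-14)$root
  # polish by bisection to the stated tolerance on the defining equation
  lo <- 0
  while (abs(f(r1)) > 1e-10 && hi - lo > 1e-16) {
    if (f(r1) > 0) hi <- r1 else lo <- r1
    r1 <- (lo + hi) / 2
  }
  list(r1 = r1, r2 = RR * r1, clamped = clamped)
}

#' Run the never/once/twice+ screening life table
#'
#' Annual-cycle multistate bookkeeping: per cycle a never-screened woman is
#' first-screened with probability \eqn{1 - e^{-r_1}}, a once-screened woman
#' is re-screened with probability \eqn{1 - e^{-r_2}}, and at most one state
#' advance occurs per cycle.
#'
#' @param r1 first-screening rate(s) per cycle (scalar or length `cycles`).
#' @param r2 re-screening rate(s) per cycle (scalar or length `cycles`).
#' @param init initial occupancy `c(S0, S1, S2)`, summing to 1.
#' @param cycles number of annual cycles (default 15: ages 30 to 45).
#' @param start_age first age label (default 30).
#' @return data frame of class `life_table`: `age, S0, S1, S2, r1, r2` with
#'   one row per age from `start_age` to `start_age + cycles`.
#' @export
run_life_table <- function(r1, r2, init = c(1, 0, 0), cycles = 15,
                           start_age = 30) {
  r1 <- rep_len(r1, cycles); r2 <- rep_len(r2, cycles)
  stopifnot(all(r1 >= 0), all(r2 >= 0), length(init) == 3L,
            abs(sum(init) - 1) < 1e-9, all(init >= 0))
  occ <- matrix(NA_real_, cycles + 1L, 3L,
                dimnames = list(NULL, c("S0", "S1", "S2")))
  occ[1L, ] <- init
  for (t in seq_len(cycles)) {
    p1 <- 1 - exp(-r1[t]); p2 <- 1 - exp(-r2[t])
    occ[t + 1L, "S0"] <- occ[t, "S0"] * (1 - p1)
    occ[t + 1L, "S1"] <- occ[t, "S1"] * (1 - p2) + occ[t, "S0"] * p1
    occ[t + 1L, "S2"] <- occ[t, "S2"] + occ[t, "S1"] * p2
  }
  res <- data.frame(age = start_age + 0:cycles, occ,
                    r1 = c(NA, r1), r2 = c(NA, r2))
  class(res) <- c("life_table", "data.frame")
  res
}

#' Life tables across posterior draws for one country's cohort
#'
#' Builds one life table per posterior draw for a cohort aged
#' `start_age` in `start_year`: each annual cycle takes the past 3-year
#' coverage draw of the age band containing the cohort's current age in the
#' current year, inverts it to (first-, re-)screening rates given the
#' cohort's current never-screened fraction and the draw's rate ratio, and
#' advances the occupancy. Initialization is either screening-naive
#' (`init = "naive"`, all mass in never-screened) or at the model's lifetime
#' coverage (`init = "model"`: \eqn{S_0 = 1 - L}, \eqn{S_1 = L},
#' \eqn{S_2 = 0} with \eqn{L} the lifetime coverage draw at the start age
#' and year — the conservative split for the screened-twice endpoint).
#'
#' @param coverage a `coverage_draws` object whose grid covers the cohort's
#'   (year, age band) path for recall `"past3y"` (and `"lifetime"` at the
#'   start when `init = "model"`) for the given country and serostatus.
#' @param rr_draws numeric vector of rate-ratio draws (recycled to the
#'   number of coverage draws).
#' @param country ISO3 code present in the coverage grid.
#' @param hiv serostatus of the cohort track (default `"neg"`).
#' @param start_age,start_year cohort age and calendar year at entry.
#' @param cycles number of annual cycles (default 15).
#' @param init `"model"` (default) or `"naive"`.
#' @return list with `tables` (array draws x (cycles+1) x 3 of occupancies)
#'   and `ages` (age labels).
#' @export
cohort_life_tables <- function(coverage, rr_draws, country, hiv = "neg",
                               start_age = 30, start_year = 2005,
                               cycles = 15, init = c("model", "naive")) {
  init <- match.arg(init)
  g <- coverage$grid
  D <- nrow(coverage$draws)
  rr_draws <- rep_len(rr_draws, D)
  find_cell <- function(year, age, recall) {
    band <- AGE_BANDS_5Y[findInterval(age, c(25, 30, 35, 40, 45, 50))]
    if (is.na(band)) stop("age ", age, " outside the modeled bands")
    i <- which(g$country == country & g$year == year &
                 g$age_group == band & g$hiv == hiv & g$recall == recall)
    if (!length(i))
      stop("coverage grid missing (", country, ", ", year, ", ", band,
           ", ", hiv, ", ", recall, ")", call. = FALSE)
    i[1L]
  }
  if (init == "model") {
    L0 <- coverage$draws[, find_cell(start_year, start_age, "lifetime")]
    occ <- cbind(1 - L0, L0, 0)
  } else {
    occ <- cbind(rep(1, D), 0, 0)
  }
  tables <- array(NA_real_, c(D, cycles + 1L, 3L),
                  dimnames = list(NULL, NULL, c("S0", "S1", "S2")))
  tables[, 1L, ] <- occ
  s3_idx <- vapply(seq_len(cycles), function(t)
    find_cell(start_year + t - 1L, start_age + t - 1L, "past3y"),
    integer(1L))
  for (t in seq_len(cycles)) {
    S3 <- coverage$draws[, s3_idx[t]]
    for (d in seq_len(D)) {
      rates <- solve_screening_rates(S3[d], occ[d, 1L], rr_draws[d])
      p1 <- 1 - exp(-rates$r1); p2 <- 1 - exp(-rates$r2)
      occ[d, ] <- c(occ[d, 1L] * (1 - p1),
                    occ[d, 2L] * (1 - p2) + occ[d, 1L] * p1,
                    occ[d, 3L] + occ[d, 2L] * p2)
    }
    tables[, t + 1L, ] <- occ
  }
  list(tables = tables, ages = start_age + 0:cycles, country = country,
       init = init)
}

#' Screened-twice summary of life-table draws
#'
#' Summarizes, across draws, the proportion screened at least twice by the
#' final age and the proportion screened at least twice among the
#' ever-screened.
#'
#' @param lt [cohort_life_tables()] output (or a list with a `tables`
#'   array).
#' @return data frame with rows `P(screened >= 2)` and
#'   `P(screened >= 2 | ever screened)`: median, lo95, hi95. The conditional
#'   row is `NA` when no draw has any screening.
#' @export
screened_twice_summary <- function(lt) {
  S <- lt$tables[, dim(lt$tables)[2L], , drop = TRUE]
  if (is.null(dim(S))) S <- matrix(S, nrow = 1,
                                   dimnames = list(NULL, c("S0", "S1", "S2")))
  twice <- S[, "S2"]
  ever <- 1 - S[, "S0"]
  cond <- ifelse(ever > 0, twice / ever, NA_real_)
  summ <- function(x) {
    if (all(is.na(x))) return(c(NA_real_, NA_real_, NA_real_))
    quantile(x, c(0.5, 0.025, 0.975), na.rm = TRUE)
  }
  out <- rbind(summ(twice), summ(cond))
  data.frame(quantity = c("P(screened >= 2)",
                          "P(screened >= 2 | ever screened)"),
             median = out[, 1L], lo95 = out[, 2L], hi95 = out[, 3L],
             row.names = NULL)
}

#' Life-table consistency check against the trend model
#'
#' Compares the ever-screened proportion at the cohort's final age with the
#' trend model's lifetime coverage at that (age band, year): the absolute
#' discrepancy per draw, summarized by its median. Mirrors the robustness
#' check of comparing life-table lifetime estimates with the time-trend
#' model's.
#'
#' @param lt [cohort_life_tables()] output.
#' @param coverage the same `coverage_draws` used to build the life tables.
#' @param hiv,start_year as passed to [cohort_life_tables()].
#' @return list `median_abs_discrepancy`, `per_draw`.
#' @export
lifetable_vs_trend <- function(lt, coverage, hiv = "neg",
                               start_year = 2005) {
  final_age <- lt$ages[length(lt$ages)]
  final_year <- start_year + final_age - lt$ages[1L]
  band <- AGE_BANDS_5Y[findInterval(final_age, c(25, 30, 35, 40, 45, 50))]
  g <- coverage$grid
  i <- which(g$country == lt$country & g$year == final_year &
               g$age_group == band & g$hiv == hiv &
               g$recall == "lifetime")
  if (!length(i))
    stop("coverage grid missing the final-age lifetime cell", call. = FALSE)
  ever_lt <- 1 - lt$tables[, dim(lt$tables)[2L], "S0"]
  disc <- abs(ever_lt - coverage$draws[, i[1L]])
  list(median_abs_discrepancy = median(disc), per_draw = disc)
}

#' Write life-table draws to CSV
#'
#' @param lt [cohort_life_tables()] output.
#' @param path output CSV `country, draw, age, S0, S1, S2`.
#' @export
write_life_tables <- function(lt, path) {
  D <- dim(lt$tables)[1L]; K <- dim(lt$tables)[2L]
  long <- data.frame(
    country = lt$country,
    draw = rep(seq_len(D), times = K),
    age = rep(lt$ages, each = D),
    S0 = as.vector(lt$tables[, , "S0"]),
    S1 = as.vector(lt$tables[, , "S1"]),
    S2 = as.vector(lt$tables[, , "S2"]))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
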