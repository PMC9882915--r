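# Synthetic "true world" generator: a known logit-linear coverage surface
# with nested region/country heterogeneity, survey tabulations drawn from it,
# auxiliary population/prevalence tables, individual screening histories with
# distinct first- and re-screening hazards, and treatment tabulations.

#' Default configuration of the synthetic world
#'
#' Describes the ground-truth coverage surface used throughout the package's
#' recovery tests: 3 regions with 2 countries each, a global lifetime
#' coverage around 12% at the 2010 reference (age 25-29, HIV-negative), a
#' rising time trend of +0.5 logits per decade, a negative recall offset so
#' past 3-year coverage is a subset of lifetime coverage, and a doubling of
#' the screening odds for women living with HIV. Re-screening rate ratios
#' default to the magnitudes reported for sub-Saharan Africa (about 34 for
#' the pooled Western/Central/Eastern region and about 21 for Southern
#' Africa).
#'
#' @param regions named list: region label -> character vector of ISO3 codes.
#' @param beta0 global intercept, logit scale.
#' @param beta_year global calendar-year slope per decade, logit scale.
#' @param alpha_age named vector of age effects for the 5-year bands
#'   (reference 25-29 must be 0).
#' @param beta_recall recall offset (past 3-year vs lifetime), must be <= 0.
#' @param gamma global HIV log-odds-ratio for screening.
#' @param sd named list of SDs for the random effects: `survey`, `country`,
#'   `region` (intercepts), `slope_country`, `slope_region` (year slopes),
#'   `hiv_country`, `hiv_region` (HIV slopes). All must be >= 0.
#' @param rr named vector of re-screening : first-screening rate ratios per
#'   region group.
#' @param r1 baseline first-screening hazard (events per woman-year).
#' @param prevalence named vector of HIV prevalence per region (flat across
#'   ages/years in the default world).
#' @param pop_base female population per (country, age band) cell.
#' @return config list consumed by [make_world()].
#' @export
world_config <- function(
    regions = list(
      "Western/Central Africa" = c("GHA", "NGA"),
      "Eastern Africa" = c("KEN", "TZA"),
      "Southern Africa" = c("ZAF", "ZWE")),
    beta0 = qlogis(0.12),
    beta_year = 0.5,
    alpha_age = c("25-29" = 0, "30-34" = 0.25, "35-39" = 0.40,
                  "40-44" = 0.45, "45-49" = 0.45),
    beta_recall = -0.7,
    gamma = log(2),
    sd = list(survey = 0.10, country = 0.30, region = 0.25,
              slope_country = 0.15, slope_region = 0.15,
              hiv_country = 0.15, hiv_region = 0.15),
    rr = c("Western/Central/Eastern Africa" = 34.1,
           "Southern Africa" = 21.2),
    r1 = 0.02,
    prevalence = c("Western/Central Africa" = 0.03,
                   "Eastern Africa" = 0.06,
                   "Southern Africa" = 0.20),
    pop_base = 1e5) {
  stopifnot(is.list(regions), length(regions) >= 1,
            alpha_age[["25-29"]] == 0,
            beta_recall <= 0, all(unlist(sd) >= 0), all(rr > 0),
            r1 >= 0, all(prevalence >= 0 & prevalence <= 1))
  list(regions = regions, beta0 = beta0, beta_year = beta_year,
       alpha_age = alpha_age, beta_recall = beta_recall, gamma = gamma,
       sd = sd, rr = rr, r1 = r1, prevalence = prevalence,
       pop_base = pop_base)
}

#' Instantiate a synthetic true world
#'
#' Draws all random effects of the ground-truth coverage surface from
#' zero-mean normals with the configured SDs. Deterministic given
#' `(config, seed)`.
#'
#' @param config a [world_config()] list.
#' @param seed integer RNG seed.
#' @return object of class `cc_world` holding the fixed effects, the drawn
#'   region/country deviations, the region map, and the rate-ratio and
#'   prevalence surfaces.
#' @export
make_world <- function(config = world_config(), seed = 1) {
  set.seed(seed)
  region <- rep(names(config$regions), lengths(config$regions))
  country <- unlist(config$regions, use.names = FALSE)
  R <- length(config$regions); C <- length(country)
  world <- list(
    config = config,
    region_names = names(config$regions),
    country = data.frame(country = country, region = region,
                         stringsAsFactors = FALSE),
    u_r = setNames(rnorm(R, 0, config$sd$region), names(config$regions)),
    v_r = setNames(rnorm(R, 0, config$sd$slope_region),
                   names(config$regions)),
    g_r = setNames(rnorm(R, 0, config$sd$hiv_region),
                   names(config$regions)),
    u_c = setNames(rnorm(C, 0, config$sd$country), country),
    v_c = setNames(rnorm(C, 0, config$sd$slope_country), country),
    g_c = setNames(rnorm(C, 0, config$sd$hiv_country), country),
    seed = seed)
  class(world) <- "cc_world"
  world
}

#' @export
print.cc_world <- function(x, ...) {
  cat("Synthetic screening world:", nrow(x$country), "countries in",
      length(x$region_names), "regions\n")
  cat("  beta0 =", round(x$config$beta0, 3),
      " beta_year =", x$config$beta_year, "/decade",
      " gamma =", round(x$config$gamma, 3), "\n")
  invisible(x)
}

world_region_of <- function(world, country) {
  i <- match(country, world$country$country)
  if (anyNA(i)) stop("country not in world: ",
                     paste(country[is.na(i)], collapse = ", "),
                     call. = FALSE)
  world$country$region[i]
}

#' True screening coverage at a grid point
#'
#' Evaluates the ground-truth coverage surface
#' \deqn{logit(p) = \beta_0 + u_r + u_c + \alpha_a +
#'   (\beta_{year} + v_r + v_c)(year - 2010)/10 +
#'   \beta_{recall} 1[recall = past3y] + (\gamma + g_r + g_c) 1[hiv = pos]}
#' Vectorized over all arguments.
#'
#' @param world a [make_world()] object.
#' @param country ISO3 code(s) on the world's grid.
#' @param year calendar year(s).
#' @param age_group 5-year band label(s).
#' @param hiv `"pos"` or `"neg"`.
#' @param recall `"lifetime"` or `"past3y"`.
#' @return coverage proportion(s) in (0, 1).
#' @export
true_coverage <- function(world, country, year, age_group,
                          hiv = "neg", recall = "lifetime") {
  n <- max(length(country), length(year), length(age_group), length(hiv),
           length(recall))
  country <- rep_len(country, n); year <- rep_len(year, n)
  age_group <- rep_len(age_group, n); hiv <- rep_len(hiv, n)
  recall <- rep_len(recall, n)
  if (!all(age_group %in% names(world$config$alpha_age)))
    stop("age_group not on the world's grid", call. = FALSE)
  stopifnot(all(hiv %in% c("pos", "neg")),
            all(recall %in% c("lifetime", "past3y")))
  reg <- world_region_of(world, country)
  cfg <- world$config
  eta <- cfg$beta0 + world$u_r[reg] + world$u_c[country] +
    cfg$alpha_age[age_group] +
    (cfg$beta_year + world$v_r[reg] + world$v_c[country]) *
      (year - 2010) / 10 +
    cfg$beta_recall * (recall == "past3y") +
    (cfg$gamma + world$g_r[reg] + world$g_c[country]) * (hiv == "pos")
  unname(expit(eta))
}

#' Default survey design for the synthetic world
#'
#' Two surveys per country (around 2008 and 2016), each reporting lifetime
#' and past 3-year screening for the five 5-year age bands; half of the
#' surveys report HIV serostatus (split pos/neg rows), the other half only
#' serostatus-mixed `"all"` rows. Effective sample sizes per stratum are
#' drawn uniformly from `n_eff_range` at simulation time, emulating
#' design-effect-deflated denominators.
#'
#' @param world a [make_world()] object.
#' @param years survey midpoints used alternately per country.
#' @param n_eff_range range of effective denominators per stratum.
#' @return data frame, one row per survey: `survey_id, country, year,
#'   survey_type, sero_reported, n_eff_lo, n_eff_hi` and the recall periods
#'   reported.
#' @export
default_survey_design <- function(world, years = c(2008, 2016),
                                  n_eff_range = c(500, 2000)) {
  countries <- world$country$country
  rows <- do.call(rbind, lapply(seq_along(countries), function(i) {
    data.frame(
      survey_id = paste0(countries[i], "-", years),
      country = countries[i],
      year = years,
      survey_type = "DHS",
      # serostatus reported in half the surveys, alternating by country
      sero_reported = if (i %% 2 == 1) c(TRUE, FALSE) else c(FALSE, TRUE),
      n_eff_lo = n_eff_range[1L], n_eff_hi = n_eff_range[2L],
      recalls = "lifetime|past3y",
      stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Simulate survey tabulations from the true world
#'
#' For each survey in the design a survey-level intercept deviation is drawn
#' (SD `config$sd$survey`); each stratum's effective screened count is
#' binomial, `k ~ Binomial(n_eff, p)`, at the stratum's true coverage. For
#' serostatus-reporting surveys, separate `hiv = "pos"` and `"neg"` rows are
#' emitted; otherwise a single `hiv = "all"` row whose success probability is
#' the prevalence-weighted mixture
#' \eqn{\pi p_{pos} + (1-\pi) p_{neg}} (the exact marginalization the trend
#' model assumes).
#'
#' @param world a [make_world()] object.
#' @param design survey design data frame (see [default_survey_design()]).
#' @param seed integer RNG seed.
#' @return validated strata data frame (see [load_strata()] for the format).
#' @export
simulate_surveys <- function(world, design = default_survey_design(world),
                             seed = 1) {
  if (!all(design$country %in% world$country$country))
    stop("design references countries absent from the world: ",
         paste(setdiff(design$country, world$country$country),
               collapse = ", "), call. = FALSE)
  set.seed(seed)
  cfg <- world$config
  ages <- names(cfg$alpha_age)
  out <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    d <- design[s, ]
    u_s <- rnorm(1, 0, cfg$sd$survey)
    recalls <- strsplit(d$recalls, "|", fixed = TRUE)[[1L]]
    pi_c <- unname(cfg$prevalence[world_region_of(world, d$country)])
    cells <- expand.grid(age_group = ages, recall = recalls,
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(cells)), function(j) {
      a <- cells$age_group[j]; rc <- cells$recall[j]
      p_neg <- adjust_logit(true_coverage(world, d$country, d$year, a,
                                          "neg", rc), u_s)
      p_pos <- adjust_logit(true_coverage(world, d$country, d$year, a,
                                          "pos", rc), u_s)
      if (d$sero_reported) {
        n <- round(runif(2, d$n_eff_lo, d$n_eff_hi))
        data.frame(hiv = c("pos", "neg"),
                   k_eff = c(rbinom(1, n[1L], p_pos),
                             rbinom(1, n[2L], p_neg)),
                   n_eff = n, age_group = a, recall = rc,
                   stringsAsFactors = FALSE)
      } else {
        n <- round(runif(1, d$n_eff_lo, d$n_eff_hi))
        p_mix <- pi_c * p_pos + (1 - pi_c) * p_neg
        data.frame(hiv = "all", k_eff = rbinom(1, n, p_mix), n_eff = n,
                   age_group = a, recall = rc, stringsAsFactors = FALSE)
      }
    })
    rows <- do.call(rbind, rows)
    rows$survey_id <- d$survey_id
    rows$country <- d$country
    rows$region <- world_region_of(world, d$country)
    rows$survey_type <- d$survey_type
    rows$year <- d$year
    out[[s]] <- rows[STRATA_COLUMNS]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  validate_strata(res)
  res
}

# shift a probability by a logit-scale offset
adjust_logit <- function(p, delta) expit(qlogis(p) + delta)

#' Simulate individual screening histories
#'
#' Each woman's time to first screen is exponential with hazard `r1`; after
#' the first screen, inter-screen gaps are exponential with hazard
#' `rr * r1` (the re-screening rate). Events are truncated at `horizon`
#' years after the start age.
#'
#' @param r1 first-screening hazard (per woman-year), >= 0.
#' @param rr re-screening : first-screening rate ratio, > 0.
#' @param n number of women.
#' @param horizon follow-up length in years.
#' @param seed integer RNG seed.
#' @param start_age age (years) at which screening exposure starts; event
#'   times are reported as ages `>= start_age`.
#' @return object of class `cc_histories`: list with `events` (list of
#'   strictly increasing event-age vectors), `start_age`, `horizon`, and
#'   per-woman `hiv` status (all `"neg"` by default) and `birth_year`.
#' @export
simulate_histories <- function(r1, rr, n, horizon, seed = 1,
                               start_age = 15) {
  stopifnot(r1 >= 0, rr > 0, n >= 1, horizon > 0)
  set.seed(seed)
  events <- vector("list", n)
  if (r1 > 0) {
    t1 <- rexp(n, rate = r1)
    r2 <- rr * r1
    for (i in seq_len(n)) {
      if (t1[i] >= horizon) { events[[i]] <- numeric(0); next }
      ev <- t1[i]
      t <- t1[i]
      repeat {
        t <- t + rexp(1, rate = r2)
        if (t >= horizon) break
        ev <- c(ev, t)
      }
      events[[i]] <- start_age + ev
    }
  } else {
    events <- replicate(n, numeric(0), simplify = FALSE)
  }
  structure(list(events = events, start_age = start_age, horizon = horizon,
                 hiv = rep("neg", n), birth_year = rep(1990, n)),
            class = "cc_histories")
}

#' @export
print.cc_histories <- function(x, ...) {
  cat("Screening histories:", length(x$events), "women, start age",
      x$start_age, "- horizon", x$horizon, "years\n")
  invisible(x)
}

#' Screening-state occupancy of simulated histories
#'
#' Proportion of women never screened, screened exactly once, and screened
#' twice or more by each elapsed time (years since `start_age`). Serves as
#' the microsimulation oracle for [run_life_table()].
#'
#' Two counting conventions are offered. `"exact"` counts screening events.
#' `"cycle"` applies the life table's bookkeeping — the state advances at
#' most once per annual cycle, so the state at integer time t is the number
#' of distinct cycles containing at least one screen, capped at 2. For
#' memoryless (exponential) hazards the `"cycle"` convention reproduces the
#' life-table recurrence exactly; `"exact"` differs from it by the
#' discretization error of order \eqn{r^2} per cycle.
#'
#' @param histories a [simulate_histories()] object.
#' @param times elapsed times (years) at which occupancy is evaluated
#'   (integers under the `"cycle"` convention).
#' @param convention `"cycle"` (life-table bookkeeping, default) or
#'   `"exact"` (raw event counts).
#' @return data frame `time, S0, S1, S2`.
#' @export
history_occupancy <- function(histories, times,
                              convention = c("cycle", "exact")) {
  convention <- match.arg(convention)
  rel <- lapply(histories$events, function(e) e - histories$start_age)
  count_by <- if (convention == "exact") {
    function(e, tt) sum(e <= tt)
  } else {
    function(e, tt) length(unique(ceiling(e[e <= tt])))
  }
  out <- t(vapply(times, function(tt) {
    nadv <- vapply(rel, count_by, numeric(1L), tt = tt)
    c(S0 = mean(nadv == 0), S1 = mean(nadv == 1), S2 = mean(nadv >= 2))
  }, numeric(3L)))
  data.frame(time = times, out)
}

#' Cross-section simulated histories into single-year-age survey strata
#'
#' Emulates a cross-sectional survey over women of the given ages: each
#' woman is assigned an integer observation age uniformly at random. Her
#' history contributes a lifetime indicator at her observation age (any
#' screen at or before it, reported under that age label) and a past-year
#' indicator for the year preceding it, reported under the label of the age
#' at which the recall window opened (`observation age - 1`). With this
#' labeling a past-year report at label `a` covers `(a, a+1]` with
#' risk-set status fixed at exact age `a` — the discretization assumed by
#' the rate-ratio likelihood, and exact for exponential screening hazards.
#' Output rows use single-year `age_group` labels with recall `"lifetime"`
#' and `"past1y"`, the input format of [build_rate_ratio_inputs()].
#'
#' @param histories a [simulate_histories()] object.
#' @param ages integer age labels to emit (default 18:29); observation ages
#'   span `min(ages)` to `max(ages) + 1`.
#' @param survey_id,country,year,survey_type stratum labels for the output.
#' @param seed integer RNG seed for the age assignment.
#' @return strata data frame.
#' @export
cross_section_histories <- function(histories, ages = 18:29,
                                    survey_id = "SIM-1", country = "KEN",
                                    year = 2015, survey_type = "OTHER",
                                    seed = 1) {
  set.seed(seed)
  n <- length(histories$events)
  obs_ages <- min(ages):(max(ages) + 1L)
  obs_age <- sample(obs_ages, n, replace = TRUE)
  rows <- lapply(obs_ages, function(a) {
    idx <- which(obs_age == a)
    if (!length(idx)) return(NULL)
    ev <- histories$events[idx]
    ever <- vapply(ev, function(e) any(e <= a), logical(1L))
    pasty <- vapply(ev, function(e) any(e > a - 1 & e <= a), logical(1L))
    life_row <- data.frame(
      age_group = as.character(a), recall = "lifetime",
      k_eff = sum(ever), n_eff = length(idx), stringsAsFactors = FALSE)
    past_row <- data.frame(
      age_group = as.character(a - 1L), recall = "past1y",
      k_eff = sum(pasty), n_eff = length(idx), stringsAsFactors = FALSE)
    out <- rbind(life_row[life_row$age_group %in% as.character(ages), ],
                 past_row[past_row$age_group %in% as.character(ages), ])
    if (!nrow(out)) return(NULL)
    out
  })
  res <- do.call(rbind, rows)
  res$survey_id <- survey_id
  res$country <- country
  res$region <- map_country_to_region(country)
  res$survey_type <- survey_type
  res$year <- year
  res$hiv <- "neg"
  res <- res[STRATA_COLUMNS]
  rownames(res) <- NULL
  validate_strata(res)
  res
}

#' Simulate auxiliary population and prevalence tables
#'
#' Population counts and HIV prevalence are taken exactly from the world's
#' configuration (flat prevalence per region, constant population per cell by
#' default); no sampling noise is added, mirroring the role of external
#' demographic estimates.
#'
#' @param world a [make_world()] object.
#' @param years calendar years to tabulate.
#' @param age_groups age band labels to tabulate.
#' @return an [aux_tables()] object covering every (country, year, age band).
#' @export
simulate_aux_tables <- function(world, years = 2000:2020,
                                age_groups = names(world$config$alpha_age)) {
  grid <- expand.grid(country = world$country$country, year = years,
                      age_group = age_groups, stringsAsFactors = FALSE)
  grid <- grid[order(grid$country, grid$year, grid$age_group), ]
  rownames(grid) <- NULL
  reg <- world_region_of(world, grid$country)
  pop <- cbind(grid, pop_f = world$config$pop_base)
  prev <- cbind(grid, prev = unname(world$config$prevalence[reg]))
  aux_tables(pop, prev)
}

#' Simulate treatment tabulations
#'
#' Draws `k_treated ~ Binomial(n_abnormal, p_treat)` per country.
#'
#' @param config data frame `country, p_treat, n_abnormal` of true
#'   per-country treatment probabilities and denominators.
#' @param seed integer RNG seed.
#' @return treatment data frame `country, k_treated, n_abnormal`.
#' @export
simulate_treatment <- function(config, seed = 1) {
  stopifnot(all(c("country", "p_treat", "n_abnormal") %in% names(config)),
            all(config$p_treat >= 0 & config$p_treat <= 1),
            all(config$n_abnormal >= 1))
  set.seed(seed)
  data.frame(country = config$country,
             k_treated = rbinom(nrow(config), config$n_abnormal,
                                config$p_treat),
             n_abnormal = config$n_abnormal,
             stringsAsFactors = FALSE)
}
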