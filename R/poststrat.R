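# Post-stratification of posterior coverage draws: population x prevalence
# weights, weighted aggregation across (country, age band, serostatus)
# strata, and imputation of countries without surveys by sampling fresh
# country-level random effects from the fitted hierarchy.

#' Specification of a post-stratified aggregate
#'
#' Describes which strata form an aggregate: the countries, years, age
#' bands and serostatus scope over which coverage is pooled. The paper-style
#' reporting aggregates are e.g. all women 30-49 in a region (serostatus
#' combined) or WLHIV 25-49 across sub-Saharan Africa.
#'
#' @param name label for the aggregate.
#' @param countries ISO3 codes included.
#' @param years calendar years (each year is aggregated separately).
#' @param age_groups 5-year band labels pooled within each year.
#' @param hiv serostatus scope: `"both"` (combined), `"pos"` or `"neg"`.
#' @return list of class `aggregate_spec`.
#' @export
aggregate_spec <- function(name, countries, years,
                           age_groups = AGE_BANDS_5Y, hiv = "both") {
  stopifnot(hiv %in% c("both", "pos", "neg"), length(countries) >= 1)
  structure(list(name = name, countries = countries, years = years,
                 age_groups = age_groups, hiv = hiv),
            class = "aggregate_spec")
}

#' Post-stratification weights from population and prevalence
#'
#' Builds the stratum weights used to pool model estimates: within each
#' (aggregate, year), the weight of stratum (country, age band, serostatus)
#' is proportional to the female population of the cell times its HIV
#' prevalence (for `hiv = "pos"`) or one minus it (for `hiv = "neg"`),
#' normalized to sum to one. Deterministic; errors name any missing
#' auxiliary cell.
#'
#' @param aux an [aux_tables()] object covering every requested stratum.
#' @param spec an [aggregate_spec()].
#' @return data frame of class `stratum_weights`: `aggregate, year, country,
#'   age_group, hiv, weight`; weights sum to 1 within each year.
#' @export
build_weights <- function(aux, spec) {
  stopifnot(inherits(spec, "aggregate_spec"))
  hiv_levels <- if (spec$hiv == "both") c("pos", "neg") else spec$hiv
  out <- lapply(spec$years, function(yr) {
    g <- expand.grid(country = spec$countries, age_group = spec$age_groups,
                     hiv = hiv_levels, stringsAsFactors = FALSE)
    w <- vapply(seq_len(nrow(g)), function(i) {
      pop <- aux_population(aux, g$country[i], yr, g$age_group[i])
      prev <- aux_prevalence(aux, g$country[i], yr, g$age_group[i])
      pop * if (g$hiv[i] == "pos") prev else (1 - prev)
    }, numeric(1L))
    if (sum(w) <= 0) stop("all-zero weights for aggregate '", spec$name,
                          "', year ", yr, call. = FALSE)
    cbind(data.frame(aggregate = spec$name, year = yr), g,
          data.frame(weight = w / sum(w)))
  })
  res <- do.call(rbind, out)
  class(res) <- c("stratum_weights", "data.frame")
  res
}

#' Pool coverage draws into post-stratified aggregates
#'
#' For every (aggregate, year, recall) and every posterior draw, forms the
#' convex combination \eqn{\sum_s w_s p_s} over the weighted strata. The
#' coverage object must contain every weighted stratum (for each recall
#' level present in its grid).
#'
#' @param coverage a `coverage_draws` object ([predict_coverage()] output,
#'   possibly row-bound with [impute_country()] output via
#'   [bind_coverage()]).
#' @param weights a [build_weights()] data frame.
#' @return list with `draws` (named list: "aggregate|year|recall" -> numeric
#'   vector of draws) and `summary` (data frame `aggregate, year, recall,
#'   median, lo95, hi95`).
#' @export
aggregate_draws <- function(coverage, weights) {
  g <- coverage$grid
  recalls <- unique(g$recall)
  keys <- unique(weights[c("aggregate", "year")])
  draws <- list()
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    wsub <- weights[weights$aggregate == keys$aggregate[i] &
                      weights$year == keys$year[i], ]
    for (rc in recalls) {
      idx <- match(paste(wsub$country, keys$year[i], wsub$age_group,
                         wsub$hiv, rc),
                   paste(g$country, g$year, g$age_group, g$hiv, g$recall))
      if (anyNA(idx))
        stop("coverage grid missing stratum (",
             paste(wsub$country[which(is.na(idx))[1L]],
                   keys$year[i], wsub$age_group[which(is.na(idx))[1L]],
                   wsub$hiv[which(is.na(idx))[1L]], rc, sep = ", "),
             ") for aggregate '", keys$aggregate[i], "'", call. = FALSE)
      agg <- as.vector(coverage$draws[, idx, drop = FALSE] %*% wsub$weight)
      key <- paste(keys$aggregate[i], keys$year[i], rc, sep = "|")
      draws[[key]] <- agg
      rows[[key]] <- data.frame(
        aggregate = keys$aggregate[i], year = keys$year[i], recall = rc,
        median = median(agg),
        lo95 = unname(quantile(agg, 0.025)),
        hi95 = unname(quantile(agg, 0.975)))
    }
  }
  list(draws = draws, summary = do.call(rbind, c(rows,
                                                 make.row.names = FALSE)))
}

#' Impute coverage draws for a country without surveys
#'
#' For each posterior draw \eqn{d}, fresh country-level effects are sampled
#' from the fitted hierarchy of that draw's region:
#' intercept \eqn{a_c^* \sim N(a_r^{(d)}, \sigma_c^{(d)2})}, year slope
#' \eqn{v_c^* \sim N(v_r^{(d)}, \tau_c^{(d)2})} and HIV slope
#' \eqn{g_c^* \sim N(g_r^{(d)}, \omega_c^{(d)2})} — the regional average
#' prediction plus the between-country uncertainty, so imputed countries
#' carry wider intervals than observed ones. Deterministic given
#' `(posterior, seed)`.
#'
#' @param posterior a [fit_trend_model()] object.
#' @param region region label fitted in the posterior.
#' @param grid data frame `year, age_group, hiv, recall` (no country
#'   column; a `country` label for the output rows is supplied separately).
#' @param country label to attach to the imputed rows.
#' @param seed integer RNG seed.
#' @return a `coverage_draws` object with a `data_tier = "imputed"`
#'   attribute.
#' @export
impute_country <- function(posterior, region, grid, country = "IMPUTED",
                           seed = 1) {
  ri <- match(region, posterior$regions)
  if (is.na(ri)) stop("region not in the fitted model: ", region,
                      call. = FALSE)
  stopifnot(all(c("year", "age_group", "hiv", "recall") %in% names(grid)))
  set.seed(seed)
  d <- posterior$draws
  D <- nrow(d)
  R <- length(posterior$regions)
  a_r <- trend_param(posterior, "a_r", R)[, ri]
  v_r <- trend_param(posterior, "v_r", R)[, ri]
  g_r <- trend_param(posterior, "g_r", R)[, ri]
  a_new <- rnorm(D, a_r, d[, "sig_c"])
  v_new <- rnorm(D, v_r, d[, "tau_c"])
  g_new <- rnorm(D, g_r, d[, "om_c"])
  ai <- match(grid$age_group, posterior$ages)
  if (anyNA(ai)) stop("age_group outside the fitted bands", call. = FALSE)
  alpha <- trend_param(posterior, "alpha", length(posterior$ages))
  br <- d[, "b_recall"]
  draws <- matrix(NA_real_, D, nrow(grid))
  for (j in seq_len(nrow(grid))) {
    tt <- (grid$year[j] - 2010) / 10
    eta <- a_new + alpha[, ai[j]] + v_new * tt +
      br * (grid$recall[j] == "past3y") +
      g_new * (grid$hiv[j] == "pos")
    draws[, j] <- expit(eta)
  }
  out_grid <- cbind(data.frame(country = country), grid)
  out_grid <- out_grid[c("country", "year", "age_group", "hiv", "recall")]
  structure(list(grid = out_grid, draws = draws),
            class = "coverage_draws", data_tier = "imputed")
}

#' Combine coverage draws objects
#'
#' Row-binds the grids (and column-binds the draws) of several
#' `coverage_draws` objects from the same posterior, e.g. observed and
#' imputed countries before regional aggregation.
#'
#' @param ... `coverage_draws` objects with equal draw counts.
#' @return a single `coverage_draws` object.
#' @export
bind_coverage <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1L), "coverage_draws")))
  D <- unique(vapply(xs, function(x) nrow(x$draws), integer(1L)))
  if (length(D) != 1L)
    stop("coverage objects have differing draw counts", call. = FALSE)
  structure(list(grid = do.call(rbind, lapply(xs, `[[`, "grid")),
                 draws = do.call(cbind, lapply(xs, `[[`, "draws"))),
            class = "coverage_draws")
}

#' Data-tier label of a country
#'
#' Mirrors the reporting rule that country-level estimates are surfaced only
#' with at least two surveys: `">=2 surveys"`, `"1 survey"` or `"imputed"`.
#'
#' @param strata strata data frame the model was fit to.
#' @param country ISO3 code.
#' @return character tier label.
#' @export
country_data_tier <- function(strata, country) {
  nsurv <- length(unique(strata$survey_id[strata$country == country]))
  if (nsurv >= 2) ">=2 surveys" else if (nsurv == 1) "1 survey"
  else "imputed"
}

#' Write aggregate summaries to CSV
#'
#' @param aggregates [aggregate_draws()] output.
#' @param path output CSV `aggregate, year, recall, median, lo95, hi95`.
#' @export
write_aggregates <- function(aggregates, path) {
  write.csv(aggregates$summary, path, row.names = FALSE)
  invisible(path)
}
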