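# Region mapping, effective-sample-size arithmetic, and readers/writers for
# the pipeline's tabular formats.

#' Pipeline vocabulary constants
#'
#' `REGIONS`: the three analysis regions. `AGE_BANDS_5Y`: the model's
#' 5-year age bands. `RECALL_LEVELS` and `HIV_LEVELS`: the admissible
#' recall-period and serostatus labels. `SURVEY_TYPES`: recognized survey
#' families. `STRATA_COLUMNS`: column order of the strata CSV format.
#'
#' @name vocabulary
#' @export
REGIONS <- c("Western/Central Africa", "Eastern Africa", "Southern Africa")

#' @rdname vocabulary
#' @export
AGE_BANDS_5Y <- c("25-29", "30-34", "35-39", "40-44", "45-49")

#' @rdname vocabulary
#' @export
RECALL_LEVELS <- c("lifetime", "past3y", "past1y")

#' @rdname vocabulary
#' @export
HIV_LEVELS <- c("pos", "neg", "all")

#' @rdname vocabulary
#' @export
SURVEY_TYPES <- c("DHS", "PHIA", "STEPS", "SAGE", "WHS", "KAIS", "SABSSM",
                  "OTHER")

# Sub-Saharan African countries by 2015 Global Burden of Disease region,
# with Western and Central Africa pooled and Mauritius assigned to Eastern
# Africa. One row per country: iso3, canonical name, region.
ssa_region_table <- function() {
  wc <- c(AGO = "Angola", BEN = "Benin", BFA = "Burkina Faso",
          CMR = "Cameroon", CPV = "Cape Verde",
          CAF = "Central African Republic", TCD = "Chad", COG = "Congo",
          COD = "Democratic Republic of the Congo",
          CIV = "Côte d'Ivoire", GNQ = "Equatorial Guinea",
          GAB = "Gabon", GMB = "Gambia", GHA = "Ghana", GIN = "Guinea",
          GNB = "Guinea-Bissau", LBR = "Liberia", MLI = "Mali",
          MRT = "Mauritania", NER = "Niger", NGA = "Nigeria",
          STP = "São Tomé and Príncipe", SEN = "Senegal",
          SLE = "Sierra Leone", TGO = "Togo")
  ea <- c(BDI = "Burundi", COM = "Comoros", DJI = "Djibouti",
          ERI = "Eritrea", ETH = "Ethiopia", KEN = "Kenya",
          MDG = "Madagascar", MWI = "Malawi", MUS = "Mauritius",
          MOZ = "Mozambique", RWA = "Rwanda", SOM = "Somalia",
          SSD = "South Sudan", TZA = "Tanzania", UGA = "Uganda",
          ZMB = "Zambia")
  sa <- c(BWA = "Botswana", SWZ = "Eswatini", LSO = "Lesotho",
          NAM = "Namibia", ZAF = "South Africa", ZWE = "Zimbabwe")
  data.frame(
    iso3 = c(names(wc), names(ea), names(sa)),
    name = c(unname(wc), unname(ea), unname(sa)),
    region = rep(REGIONS, times = c(length(wc), length(ea), length(sa))),
    stringsAsFactors = FALSE)
}

# Accepted aliases (lower-cased) beyond the canonical names above.
country_alias_table <- function() {
  c("cote d'ivoire" = "CIV", "ivory coast" = "CIV", "cabo verde" = "CPV",
    "swaziland" = "SWZ", "the gambia" = "GMB",
    "united republic of tanzania" = "TZA", "drc" = "COD",
    "dr congo" = "COD", "congo, dem. rep." = "COD",
    "republic of the congo" = "COG", "sao tome and principe" = "STP",
    "car" = "CAF")
}

#' Normalize a country identifier to an ISO3 code
#'
#' Accepts ISO3 codes or country names (canonical or common aliases) for the
#' sub-Saharan African countries covered by the pipeline.
#'
#' @param country character vector of ISO3 codes or names.
#' @return character vector of ISO3 codes.
#' @export
country_to_iso3 <- function(country) {
  tab <- ssa_region_table()
  alias <- country_alias_table()
  vapply(as.character(country), function(x) {
    if (toupper(x) %in% tab$iso3) return(toupper(x))
    hit <- match(tolower(x), tolower(tab$name))
    if (!is.na(hit)) return(tab$iso3[hit])
    if (tolower(x) %in% names(alias)) return(unname(alias[tolower(x)]))
    stop("unknown country: '", x, "' (not in the packaged sub-Saharan ",
         "Africa region table)", call. = FALSE)
  }, character(1L), USE.NAMES = FALSE)
}

#' Map a country to its analysis region
#'
#' Regions follow the 2015 Global Burden of Disease classification with
#' Western and Central Africa combined into one region and Mauritius assigned
#' to Eastern Africa.
#'
#' @param country ISO3 code or country name (vectorized).
#' @return one of `"Western/Central Africa"`, `"Eastern Africa"`,
#'   `"Southern Africa"` per element.
#' @examples
#' map_country_to_region("Mauritius")      # "Eastern Africa"
#' map_country_to_region(c("GHA", "ZAF"))
#' @export
map_country_to_region <- function(country) {
  tab <- ssa_region_table()
  iso <- country_to_iso3(country)
  tab$region[match(iso, tab$iso3)]
}

#' Effective sample size of a survey-weighted proportion
#'
#' Inverts the variance of a weighted proportion to the sample size a simple
#' random sample of equal information would have:
#' \eqn{n_{eff} = \hat{p}(1-\hat{p})/se^2}. When only a survey-adjusted
#' confidence interval is available, the standard error is recovered from the
#' interval half-width under a normal approximation,
#' \eqn{se = (upper - lower) / (2 z_{level})} with \eqn{z} the exact standard
#' normal quantile for the stated level.
#'
#' @param p_hat weighted proportion, strictly inside (0, 1). For observed
#'   proportions of exactly 0 or 1 apply [adjust_boundary_proportion()] first.
#' @param se standard error of `p_hat` (give either `se` or `ci`).
#' @param ci numeric vector `c(lower, upper, level)`, e.g.
#'   `c(0.15, 0.25, 0.95)`; must bracket `p_hat`.
#' @return effective sample size (positive real, not rounded; see
#'   [integerize_counts()]).
#' @examples
#' effective_sample_size(0.5, se = 0.05)               # 100
#' effective_sample_size(0.2, ci = c(0.15, 0.25, 0.95)) # ~245.9
#' @export
effective_sample_size <- function(p_hat, se = NULL, ci = NULL) {
  stopifnot(length(p_hat) == 1L, is.finite(p_hat))
  if (p_hat <= 0 || p_hat >= 1)
    stop("p_hat must lie strictly in (0, 1); for boundary proportions ",
         "apply adjust_boundary_proportion() before computing the ",
         "effective sample size", call. = FALSE)
  if (is.null(se) == is.null(ci))
    stop("give exactly one of 'se' or 'ci'", call. = FALSE)
  if (!is.null(ci)) {
    stopifnot(length(ci) == 3L, all(is.finite(ci)))
    lower <- ci[1L]; upper <- ci[2L]; level <- ci[3L]
    if (upper <= lower) stop("inverted confidence interval", call. = FALSE)
    if (level <= 0 || level >= 1) stop("CI level must be in (0,1)")
    if (p_hat < lower || p_hat > upper)
      stop("confidence interval does not bracket p_hat", call. = FALSE)
    z <- qnorm(1 - (1 - level) / 2)
    se <- (upper - lower) / (2 * z)
  }
  stopifnot(is.finite(se), se > 0)
  p_hat * (1 - p_hat) / se^2
}

#' Continuity adjustment for boundary proportions
#'
#' Replaces an observed proportion of exactly 0 or 1 by
#' \eqn{\tilde{p} = (k + 0.5) / (n + 1)} so that a finite effective sample
#' size can be computed.
#'
#' @param k screened count, `n` denominator (nominal, pre-adjustment).
#' @param n denominator.
#' @return adjusted proportion in (0, 1).
#' @export
adjust_boundary_proportion <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  (k + 0.5) / (n + 1)
}

#' Integer counts for an exact binomial likelihood
#'
#' The trend model uses an exact binomial likelihood and therefore needs
#' integer counts. The effective denominator is rounded to the nearest
#' integer (at least 1) and the numerator to `round(p_hat * n)`, clamped to
#' `[0, n]`, preserving the observed proportion and the design-adjusted
#' information.
#'
#' @param k_eff effective screened count (real), `n_eff` effective
#'   denominator (real). Vectorized.
#' @param n_eff effective denominator.
#' @return list with integer vectors `k` and `n`.
#' @export
integerize_counts <- function(k_eff, n_eff) {
  stopifnot(length(k_eff) == length(n_eff), all(n_eff > 0),
            all(k_eff >= 0), all(k_eff <= n_eff + 1e-9))
  n <- pmax(1L, as.integer(round(n_eff)))
  p_hat <- k_eff / n_eff
  k <- pmin(n, pmax(0L, as.integer(round(p_hat * n))))
  list(k = k, n = n)
}

#' @rdname vocabulary
#' @export
STRATA_COLUMNS <- c("survey_id", "country", "region", "survey_type", "year",
                    "age_group", "recall", "hiv", "k_eff", "n_eff")

# Valid age-group labels: the model's 5-year bands plus single years 15-49
# (used by the rate-ratio inputs).
valid_age_groups <- function() c(AGE_BANDS_5Y, as.character(15:49))

#' Validate a table of survey strata
#'
#' Checks the column contract and the row invariants of the stratum
#' observation format: counts `0 <= k_eff <= n_eff`, year in `[2000, 2020]`,
#' known age-group/recall/HIV labels, region consistent with the packaged
#' country-region table. If auxiliary tables are supplied, every `hiv = "all"`
#' row must have a resolvable prevalence for its (country, year, age band).
#'
#' @param strata data frame in the strata format (see [load_strata()]).
#' @param aux optional [aux_tables()] object for prevalence resolution.
#' @return the validated data frame, invisibly; errors name offending rows.
#' @export
validate_strata <- function(strata, aux = NULL) {
  miss <- setdiff(STRATA_COLUMNS, names(strata))
  if (length(miss))
    stop("strata table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(strata$k_eff) || !is.numeric(strata$n_eff) ||
      !is.numeric(strata$year))
    stop("columns year, k_eff, n_eff must be numeric", call. = FALSE)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("invalid strata row(s) [", paste(rows, collapse = ", "), "]: ",
           what, call. = FALSE)
  }
  bad(!is.finite(strata$n_eff) | strata$n_eff <= 0, "n_eff must be > 0")
  bad(!is.finite(strata$k_eff) | strata$k_eff < 0 |
        strata$k_eff > strata$n_eff + 1e-9, "requires 0 <= k_eff <= n_eff")
  bad(strata$year < 2000 | strata$year > 2020, "year outside [2000, 2020]")
  bad(!strata$age_group %in% valid_age_groups(), "unknown age_group label")
  bad(!strata$recall %in% RECALL_LEVELS, "unknown recall label")
  bad(!strata$hiv %in% HIV_LEVELS, "unknown hiv label")
  bad(!strata$survey_type %in% SURVEY_TYPES, "unknown survey_type")
  expected_region <- map_country_to_region(strata$country)
  bad(strata$region != expected_region,
      "region inconsistent with country-region table")
  # a survey contributes either serostatus-split rows or one "all" row per
  # (age, recall) cell, never both
  key <- paste(strata$survey_id, strata$age_group, strata$recall)
  for (k in unique(key)) {
    h <- strata$hiv[key == k]
    if ("all" %in% h && any(c("pos", "neg") %in% h))
      stop("survey cell '", k, "' mixes hiv='all' with serostatus-split ",
           "rows; a survey must contribute one or the other", call. = FALSE)
  }
  if (!is.null(aux)) {
    allr <- which(strata$hiv == "all")
    for (i in allr) {
      pr <- aux_prevalence(aux, strata$country[i], strata$year[i],
                           strata$age_group[i], required = FALSE)
      if (is.na(pr))
        stop("strata row ", i, ": hiv='all' but no prevalence entry for (",
             strata$country[i], ", ", strata$year[i], ", ",
             strata$age_group[i], ") in the auxiliary tables",
             call. = FALSE)
    }
  }
  invisible(strata)
}

#' Read survey strata from CSV
#'
#' Expects the header
#' `survey_id,country,region,survey_type,year,age_group,recall,hiv,k_eff,n_eff`
#' with one row per survey x age-group x recall x serostatus cell. All rows
#' are validated on load (see [validate_strata()]).
#'
#' @param path CSV file path.
#' @param aux optional [aux_tables()] object; when given, `hiv = "all"` rows
#'   must be resolvable against its prevalence table.
#' @return data frame of validated strata.
#' @export
load_strata <- function(path, aux = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("year", "k_eff", "n_eff"), names(df))) {
    suppressWarnings(num <- as.numeric(df[[col]]))
    if (anyNA(num) && !anyNA(df[[col]]))
      stop("non-numeric values in column '", col, "'", call. = FALSE)
    df[[col]] <- num
  }
  validate_strata(df, aux = aux)
  df[STRATA_COLUMNS]
}

#' Write survey strata to CSV
#'
#' Counts are written as decimal text with 15 significant digits so that a
#' write/load round trip reproduces the table exactly.
#'
#' @param strata validated strata data frame.
#' @param path output CSV path.
#' @export
write_strata <- function(strata, path) {
  validate_strata(strata)
  out <- strata[STRATA_COLUMNS]
  for (col in c("year", "k_eff", "n_eff"))
    out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                         scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Auxiliary population and HIV-prevalence tables
#'
#' Bundles the two auxiliary surfaces the pipeline queries: female population
#' counts and HIV prevalence among women, both indexed by (country, year,
#' age group). These emulate the roles of UN World Population Prospects
#' population counts and UNAIDS prevalence estimates.
#'
#' @param population data frame `country, year, age_group, pop_f`.
#' @param prevalence data frame `country, year, age_group, prev`.
#' @return object of class `aux_tables`.
#' @export
aux_tables <- function(population, prevalence) {
  stopifnot(all(c("country", "year", "age_group", "pop_f") %in%
                  names(population)),
            all(c("country", "year", "age_group", "prev") %in%
                  names(prevalence)))
  if (any(population$pop_f < 0)) stop("population counts must be >= 0")
  if (any(prevalence$prev < 0 | prevalence$prev > 1))
    stop("prevalence must lie in [0, 1]")
  structure(list(population = population, prevalence = prevalence),
            class = "aux_tables")
}

#' @export
print.aux_tables <- function(x, ...) {
  cat("aux_tables:", nrow(x$population), "population cells,",
      nrow(x$prevalence), "prevalence cells\n")
  invisible(x)
}

aux_cell <- function(df, value_col, country, year, age_group, required,
                     what) {
  i <- which(df$country == country & df$year == year &
               df$age_group == age_group)
  if (!length(i)) {
    if (required)
      stop("no ", what, " entry for (", country, ", ", year, ", ",
           age_group, ")", call. = FALSE)
    return(NA_real_)
  }
  df[[value_col]][i[1L]]
}

#' Look up HIV prevalence / population for one stratum
#'
#' @param aux an [aux_tables()] object.
#' @param country ISO3 code; `year` calendar year; `age_group` band label.
#' @param year calendar year.
#' @param age_group age band label.
#' @param required error (default) or return `NA` when the cell is absent.
#' @return scalar prevalence (proportion) or population count.
#' @export
aux_prevalence <- function(aux, country, year, age_group, required = TRUE) {
  aux_cell(aux$prevalence, "prev", country, year, age_group, required,
           "prevalence")
}

#' @rdname aux_prevalence
#' @export
aux_population <- function(aux, country, year, age_group, required = TRUE) {
  aux_cell(aux$population, "pop_f", country, year, age_group, required,
           "population")
}

#' Read auxiliary tables from CSV
#'
#' @param population_path CSV `country,year,age_group,pop_f`.
#' @param prevalence_path CSV `country,year,age_group,prev`.
#' @return [aux_tables()] object.
#' @export
load_aux_tables <- function(population_path, prevalence_path) {
  aux_tables(read.csv(population_path, stringsAsFactors = FALSE),
             read.csv(prevalence_path, stringsAsFactors = FALSE))
}

#' Write auxiliary tables to CSV
#'
#' @param aux [aux_tables()] object.
#' @param population_path,prevalence_path output CSV paths.
#' @export
write_aux_tables <- function(aux, population_path, prevalence_path) {
  write.csv(aux$population, population_path, row.names = FALSE)
  write.csv(aux$prevalence, prevalence_path, row.names = FALSE)
  invisible(NULL)
}

#' Read / write treatment tabulations
#'
#' Treatment CSV format: `country,k_treated,n_abnormal`, one row per country,
#' counting women treated for pre-cancer among those reporting an abnormal
#' (non-cancer) screening result.
#'
#' @param path CSV path.
#' @return data frame with integer counts.
#' @export
load_treatment <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("country", "k_treated", "n_abnormal"), names(df))
  if (length(miss))
    stop("treatment table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$k_treated < 0 | df$n_abnormal < 1 |
                 df$k_treated > df$n_abnormal)
  if (length(bad))
    stop("invalid treatment row(s) [", paste(bad, collapse = ", "),
         "]: requires 0 <= k_treated <= n_abnormal, n_abnormal >= 1")
  df
}

#' @rdname load_treatment
#' @param treatment data frame `country,k_treated,n_abnormal`.
#' @export
write_treatment <- function(treatment, path) {
  write.csv(treatment, path, row.names = FALSE)
  invisible(path)
}
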