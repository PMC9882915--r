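# ccscreen

Estimation pipeline for **cervical cancer (CC) screening coverage trends in
sub-Saharan Africa**, for epidemiologists and modellers working with
stratified cross-sectional survey tabulations rather than individual-level
microdata. The package implements four linked analyses:

1. **Coverage trends.** A four-level Bayesian multilevel binomial logistic
   regression (survey ⊂ country ⊂ region ⊂ sub-Saharan Africa) jointly
   models lifetime and past 3-year screening. For a stratum in survey *s*,
   country *c*, region *r*:

   ```
   k ~ Binomial(n, p)
   logit p(neg) = β₀ + u_r + u_c + u_s + α_age
                  + (β_year + v_r + v_c) · (year − 2010)/10
                  + β_recall · 1[recall = past 3 years]
   logit p(pos) = logit p(neg) + (γ + g_r + g_c)
   ```

   Surveys that did not record HIV serostatus contribute mixed strata whose
   success probability is marginalized over serostatus with external HIV
   prevalence π: `p(all) = π·p(pos) + (1−π)·p(neg)`. The recall offset
   β_recall is constrained ≤ 0 (a past 3-year report logically implies a
   lifetime report). Effective sample sizes from survey design effects (or
   inverted survey-adjusted confidence intervals) replace nominal counts.

2. **Post-stratification.** Posterior coverage draws are pooled to broader
   age bands, combined serostatus, and country/region/SSA aggregates with
   population × prevalence weights; countries without surveys are imputed by
   sampling fresh country-level random effects from the fitted hierarchy, so
   their intervals are honestly wider.

3. **Re-screening by age 45.** Because surveys do not ask about screening
   frequency, the re-screening : first-screening rate ratio RR is identified
   from cross-sectional data by relating lifetime-coverage increments
   between successive single-year ages (18–29) to past-year screening
   fractions, in a hierarchical binomial model. A never/once/twice+
   multistate life table then subjects a cohort aged 30 in 2005 to the
   resulting first- and re-screening rates through 2020.

4. **Treatment coverage.** Country-level counts of women treated for
   pre-cancer among those with an abnormal, non-cancer screening result are
   pooled with a Bayesian logistic random-effects meta-analysis.

Because real survey microdata are access-restricted, the package ships a
**synthetic-data generator with known ground truth** (`make_world()`,
`simulate_surveys()`, `simulate_histories()`, …). Every stage is validated
against that truth: parameter recovery, a microsimulation oracle for the
life table, conjugate-posterior oracles for the meta-analysis, and posterior
predictive checks. Models are fit with JAGS via `rjags`.

## Worked example

```r
library(ccscreen)

world  <- make_world(world_config(), seed = 1)      # known truth
strata <- simulate_surveys(world, default_survey_design(world), seed = 1001)
aux    <- simulate_aux_tables(world)

fit <- fit_trend_model(strata, aux,
                       mcmc_config(chains = 4, warmup = 2500, iter = 800,
                                   thin = 20, seed = 1))
print(fit)
#> Trend model posterior: 3200 draws, 180 strata, 12 surveys, 6 countries, 3 regions
#>   max split-Rhat: 1.0023 (converged)
#>            2.5%    50%  97.5%
#> b0       -2.723 -2.020 -1.149
#> b_year   -0.225  0.548  1.338
#> b_recall -0.717 -0.693 -0.669
#> gam       0.312  0.768  1.219
```

The generating truth was `b0 = logit(0.12) = −1.99`, `b_year = 0.5` per
decade, `b_recall = −0.7` and `gam = ln 2 = 0.69`: each 95% credible
interval covers it. Downstream:

```r
ppc <- posterior_predictive_check(fit, seed = 2001)
ppc$prop_inside           # 0.967: strata inside central 95% intervals

w  <- build_weights(aux, aggregate_spec("Eastern Africa",
                                        c("KEN", "TZA"), 2020))
cov <- predict_coverage(fit, prediction_grid(c("KEN", "TZA"), 2020))
aggregate_draws(cov, w)$summary
#>        aggregate year   recall median  lo95  hi95
#>   Eastern Africa 2020 lifetime  0.281 0.219 0.347
#>   Eastern Africa 2020   past3y  0.165 0.125 0.212
```
(proportions screened among women 25–49, serostatus combined)

The numbered scripts under `analysis/` chain the full pipeline
(simulate → fit trends → post-stratify → life table → treatment
meta-analysis → validate) from one YAML config with explicit seeds; each
stage writes CSV artifacts plus a JSON manifest under `results/`:

```sh
Rscript analysis/01_simulate.R analysis/config.yaml
Rscript analysis/02_fit_trends.R analysis/config.yaml
# ... through analysis/06_validate.R
```

## Limitations

The synthetic worlds are simpler than real survey collections (no
survey-type confounding, no nonresponse, flat prevalence surfaces), so green
tests demonstrate the correctness of the estimation machinery, not the
field accuracy of any particular published estimate. The packaged
four-country treatment table uses synthetic denominators and is labelled as
such. See the methods vignette (`vignettes/ccscreen-methods.Rmd`) for the
full model descriptions, parameter defaults, and design decisions.
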