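---
title: "Models and methods behind ccscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ccscreen estimates cervical cancer (CC) screening coverage trends among
women aged 25–49 in sub-Saharan Africa from stratified cross-sectional
survey tabulations, then derives three downstream quantities: coverage
aggregates for policy-relevant populations, the proportion of women
screened at least twice by age 45, and pre-cancer treatment coverage. This
vignette documents the models, the parameters that matter, the
synthetic-data generator used for validation, and the design decisions
taken where more than one reasonable choice existed.

## 1. Data model and pre-processing

The unit of likelihood is a **survey stratum**: one (survey, country, year,
5-year age band, recall period, HIV serostatus) cell with an effective
screened count `k_eff` and an effective denominator `n_eff`. Effective
sample sizes absorb the survey design effect; where only a survey-adjusted
confidence interval is available, `effective_sample_size()` inverts it
under a normal approximation with the *exact* standard normal quantile for
the stated level (not 1.96), an explicit choice since source reports rarely
state their interval construction. Observed proportions of exactly 0 or 1
receive the continuity adjustment `(k + 0.5)/(n + 1)` before inversion.

The binomial likelihood needs integer counts: `n_eff` is rounded to the
nearest integer (minimum 1) and `k` to `round(p̂·n)` clamped to `[0, n]`,
which preserves the observed proportion and the design-adjusted
information. A stratum whose `n_eff` rounds to zero carries no information
and is dropped, so adding such a stratum never perturbs the posterior.

Regions follow the 2015 Global Burden of Disease classification with
Western and Central Africa pooled (few surveys) and Mauritius assigned to
Eastern Africa. Country identifiers are normalized to ISO3; names and
common aliases are accepted.

## 2. The coverage trend model

Four nested levels — survey ⊂ country ⊂ region ⊂ sub-Saharan Africa — with
random intercepts at every level, hierarchical year slopes at country and
region level, age fixed effects (reference 25–29), a recall-period offset,
and an HIV log-odds-ratio with its own country/region hierarchy. Lifetime
and past 3-year strata are modeled jointly; the two reports from one
survey are treated as independent binomials because the source tabulations
carry no joint structure. Hierarchical year slopes at region level are
essential: regional trends differ qualitatively (Southern Africa rising
while the others are flat), which a single global slope cannot express.

**Serostatus marginalization.** Most surveys do not record HIV serostatus.
Their strata enter as `hiv = "all"` rows with success probability
`π·p(pos) + (1−π)·p(neg)`, π taken from external prevalence tables. This is
an exact marginalization, so surveys with and without serostatus
information combine coherently; a validation rule refuses inputs where one
survey contributes both split and mixed rows for the same cell
(double-counting).

**Priors.** Normal(0, 2.5²) on fixed effects; half-Normal(0, 1) on all
random-effect SDs — weakly informative defaults for logit-scale
hierarchical models. The recall offset is truncated ≤ 0: a past 3-year
screen logically implies a lifetime screen, so predicted past 3-year
coverage can never exceed lifetime coverage, draw-wise. Whether the
original analyses imposed this sign constraint is unknowable from public
material; we state it as our own modeling commitment.

**Computation.** Models are fit in JAGS. We use the *hierarchically
centered* parameterization — each level's absolute effect is drawn around
its parent's (`a_s ~ N(a_c + v_c·t_s, σ_s²)`, `a_c ~ N(a_r, σ_c²)`,
`a_r ~ N(β₀, σ_r²)`, and likewise for year and HIV slopes) — rather than
the non-centered form favored by Hamiltonian samplers. With one-at-a-time
Gibbs/slice updates and data-rich groups, centering gives near-conjugate
updates for all upper-level location parameters; in our experiments the
non-centered form produced split-R̂ up to 9 on the default problem while
the centered form reaches R̂ ≤ 1.01. Folding the survey-year slope into
the survey-level mean is an algebraically identical factorization that
removes the remaining intercept–slope coupling. Deviations (`u_c = a_c −
a_r` etc.) are recovered by differencing. Defaults: 4 chains × (1000
warmup + 1000 draws); for R̂ ≤ 1.01 on all variance components we
recommend thinned longer runs (e.g. `thin = 20`, warmup 2500), which the
test suite uses. Per-chain seeds are explicit (`seed + chain − 1`), so
runs are bit-reproducible.

**Checks.** `posterior_predictive_check()` simulates replicate counts
in-sample (including survey effects) and reports the share of strata
inside central 95% predictive intervals plus standardized residuals. Under
the true model 90–99% of strata should fall inside; a count corrupted to
its denominator is flagged with |z| well above 4.

## 3. Post-stratification and imputation

Weights within any aggregate are population × prevalence shares:
`pop·π` for HIV-positive strata and `pop·(1−π)` for HIV-negative, normalized
to one within each (aggregate, year). Aggregation is a convex combination
per posterior draw, so nested aggregation (country → region → SSA)
coincides with direct aggregation under composed weights, and reported
intervals are genuine posterior quantiles of the aggregate. Age-specific
prevalence is used throughout (whether published aggregates used age-specific
or all-ages prevalence is not stated; age-specific is the more faithful
weighting).

Countries without surveys are imputed per draw by sampling fresh
country-level effects from that draw's hierarchy — intercept
`N(a_r, σ_c²)`, year slope `N(v_r, τ_c²)`, HIV slope `N(g_r, ω_c²)` — so
imputed countries inherit the regional mean *and* the between-country
spread; their intervals are systematically wider than observed countries'.
Country outputs carry a data-tier label (≥2 surveys / 1 survey / imputed);
by convention only tier-1 countries are surfaced in country-level tables.

## 4. Re-screening and the life table

Surveys do not ask how often a woman has been screened, so the WHO
twice-by-45 indicator is computed indirectly.

**Rate ratio.** Under stationary exponential hazards — first screens at
rate r₁, re-screens at rate r₂ = RR·r₁ — lifetime coverage follows
`L(a+1) = L(a) + (1−L(a))(1−e^{−r₁})`, and a past-year report indexed by
the age `a` at which its window opened has probability
`(1−L(a))(1−e^{−r₁}) + L(a)(1−e^{−RR·r₁})`. The hierarchical fit places a
random effect on log r₁ per survey (half-Normal(0,1) SD, Normal(−3, 2²)
intercept) and one log RR per region group (Normal(0, 2²)): Western,
Central and Eastern Africa pooled; Southern Africa separate. Analyses are
restricted to ages 18–29, where cohort/period biases in the increment
identification are smallest; the crude moment estimator
`RR̂ = ln(1−q_re)/ln(1−q₁)` is reported for diagnostics only, with
physically impossible records (negative increments, past-year below the
increment) flagged and excluded from the crude estimator but retained for
the Bayesian fit, whose binomial likelihood accounts for the sampling
noise that produces them.

A discretization convention matters here: the likelihood reads a past-year
report at age label *a* as covering (a, a+1] with risk-set status fixed at
exact age *a*. The synthetic cross-section generator uses exactly this
labeling (a woman observed at integer age a+1 reports her past year under
label a), which makes the likelihood exact for memoryless hazards. Real
surveys label by completed age, a half-year misalignment whose bias is of
the order of one year's coverage increment — a known approximation, not
corrected here.

**From coverage to rates.** Given a past 3-year coverage draw S₃, the
current never-screened fraction S₀ and a rate-ratio draw, the
first-screening rate solves
`S₃ = S₀(1−e^{−3r₁}) + (1−S₀)(1−e^{−3·RR·r₁})` — among the never-screened
any window screen is a first screen; among the ever-screened, window
screening occurs at the re-screening rate. The right side is strictly
increasing in r₁; the root is found by bracketed bisection to |Δ| < 1e−10,
with S₃ ≥ 1 clamped and flagged.

**Life table.** Annual cycles from age 30 (year 2005) to 45 (2020), states
never/once/twice+; per cycle, never→once with probability 1−e^{−r₁},
once→twice+ with probability 1−e^{−r₂}, at most one advance per cycle
(error O(r²) per cycle at observed coverage levels). Each cycle's rates
come from the coverage draw at the age band containing the cohort's
current age in the current year. Initialization defaults to the model's
lifetime coverage at (30, 2005): S₀ = 1−L, S₁ = L, S₂ = 0 — women screened
before 30 exist, and placing all of them in "once" is conservative for the
screened-twice endpoint. A `naive` switch starts the cohort unscreened.
The microsimulation oracle (`simulate_histories()` +
`history_occupancy(convention = "cycle")`) applies the same
one-advance-per-cycle bookkeeping, under which the equivalence with the
recurrence is exact for exponential hazards; `convention = "exact"` counts
raw events and quantifies the discretization error instead.

As a robustness check, `lifetable_vs_trend()` compares the life table's
ever-screened proportion at the final age with the trend model's lifetime
coverage there. On hazard-coherent synthetic data this discrepancy is at
the solver tolerance; when coverage comes from the logit-linear trend
model (which is not exactly hazard-coherent) discrepancies of a few
percentage points are expected and reported, not hidden.

## 5. Treatment meta-analysis

`k_c ~ Binomial(n_c, expit(μ + u_c))`, `u_c ~ N(0, σ²)`, μ ~ N(0, 2.5²),
σ ~ half-N(0, 1). The pooled summary is the typical-country proportion
expit(μ); a `population` option reports the population-average
`E[expit(μ + u)]` instead, which is smaller under heterogeneity for
proportions above one half. Observations are sorted by country before
fitting so row order can never affect the sampler. The packaged
four-country demonstration table reproduces published per-country
percentages (77–90%) with *synthetic* denominators, since the true
denominators (113 women in total) are not public; it is labelled
accordingly and used only to exercise the machinery.

## 6. The synthetic world and what passing tests show

`world_config()` fixes the study conditions used across all tests:
3 regions × 2 countries × 2 surveys per country (≈180 strata), five age
bands, effective denominators 500–2000 per stratum, β₀ = logit(0.12),
β_year = +0.5/decade, recall offset −0.7, HIV odds ratio 2, random-effect
SDs 0.10–0.30, flat regional HIV prevalences (3%, 6%, 20%), and
re-screening rate ratios of 34.1 (pooled Western/Central/Eastern) and 21.2
(Southern) with r₁ = 0.02/year and a sexual-debut floor of age 15 for
screening exposure. These magnitudes mirror the published estimates for
the region so that the recovery tests run under realistic conditions; the
scale (6 countries, 12 surveys) keeps a full MCMC fit at ~20 s on one CPU,
and the test suite's ten-replicate recovery study within minutes.

Serostatus-unknown strata are generated from the *exact*
prevalence-weighted mixture rather than by thinning individuals, matching
the model's marginalization assumption so that recovery tests are
well-posed. The generator deliberately omits survey-type confounding,
nonresponse, demographic change and HIV incidence dynamics: green tests
certify the estimation machinery (identifiability, calibration, coherence
between stages), not the field accuracy of any published estimate, which
would require the restricted microdata.

## 7. Numerical and interface choices

* Year is centered at 2010 and scaled per decade, decorrelating intercepts
  and slopes over the 2000–2020 window.
* Split-R̂ is computed for every monitored scalar; fits warn and set
  `converged = FALSE` above 1.05 (JAGS has no divergence diagnostic; the
  count is reported as not applicable).
* `solve_screening_rates()` brackets then bisects; ties and boundaries:
  S₃ = 0 maps to rates (0, 0), S₃ ≥ 1 is clamped with a flag.
* Stage artifacts are plain CSV plus JSON manifests carrying a config
  fingerprint, the seed, package version and upstream-manifest
  fingerprints — a reproducibility chain without a binary store. The
  analysis scripts under `analysis/` (driven by one YAML config with
  explicit seeds) are the pipeline's command-line surface.
* Sensitivity switches mirror common robustness analyses: restricting to
  years ≥ 2010 (`year_min`) and a WHS survey-type fixed effect
  (`whs_effect`).

## 8. Known limitations

Correlated lifetime/past 3-year reports from the same respondents are
treated as independent binomials. The rate-ratio identification assumes
stationary hazards over ages 18–29 and is biased under strong cohort or
period effects (the age restriction mitigates but does not remove this;
the generator's time-varying r₁ hook allows such scenarios to be
constructed). The life table ignores mortality and HIV-differential
attrition, and caps state resolution at "twice or more". Treatment
analyses pool only countries with data and cannot speak to treatment
modality.
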