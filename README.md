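# ccitrend

Trends, 2030 projections and equity analysis of composite RMNCH coverage
in low- and middle-income countries.

Household surveys (DHS, MICS) measure coverage of essential reproductive,
maternal, newborn and child health (RMNCH) interventions, summarised by the
Countdown **composite coverage index** (CCI) — the weighted average of four
intervention domains:

```
CCI = 1/4 [ DFPSm + (ANC4 + SBA)/2 + (BCG + 2·DPT3 + MSL)/4 + (ORS + CAREP)/2 ]
```

The operational universal-health-coverage target is CCI ≥ 80% by 2030.
Because surveys are sparse (many countries have a single data point in two
decades), `ccitrend` estimates trends with a **Bayesian hierarchical linear
model on logit-transformed CCI**,

```
logit(y) = α + u_region + u_country + β₁·year + β₂ᵀ·stratum
           + β₃·SDI + β₄·GGDPH + β₅·GDPC + ε,   ε ~ N(0, τ²)
```

with country-in-region random intercepts, stratum dummies (national /
urban / rural, wealth quintiles Q1–Q5, or maternal education), and
standardised country-year covariates. Fitting is by a fully conjugate
blocked Gibbs sampler written for this model (joint draws of all location
parameters; gamma or half-Cauchy(0, 25) hyperpriors). On top of the fit the
package provides:

- projections to 2030 with 95% credible intervals and the probability of
  reaching the 80% target (`predict_cci()`, `prob_target()`,
  `count_on_track()`; "on track" means P ≥ 0.70);
- regional aggregation per posterior draw by DerSimonian–Laird
  random-effects meta-analysis or weighted means (`aggregate_region()`);
- equity metrics with full uncertainty: urban–rural gaps and the slope
  index of inequality via ridit scoring (`urban_rural_gap()`, `sii()`,
  `inequality_table()`);
- model checking: iterative VIF screening, DIC, posterior predictive
  checks, Gelman–Rubin PSRF, prior-sensitivity comparison;
- a synthetic survey-panel generator with known ground truth
  (`simulate_bundle()`) emulating 70 countries in 9 regions with realistic
  survey sparsity, so the whole pipeline is testable without external data;
- a reproducible end-to-end pipeline (`run_pipeline()`) writing CSV outputs
  and a JSON manifest.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for fits, `autoplot()` for projections and traces.

## Worked example

```r
library(ccitrend)
library(dplyr)

# a small synthetic monitoring scenario with known truth
cfg    <- scenario_config(n_regions = 3, countries_per_region = 4,
                          surveys_min = 2, surveys_max = 5, seed = 2024)
bundle <- simulate_bundle(cfg)           # 102 observed stratum-level CCIs

fit <- fit_cci_model(bundle$panel, bundle$covariates, variant = "residence",
                     chains = 4, iter = 2000, seed = 1)
tidy(fit)
#> # A tibble: 7 × 6
#>   term            estimate std.error conf.low conf.high  psrf
#>   <chr>              <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 (Intercept)      -0.0631    0.300    -0.596     0.453 1.000
#> 2 year              0.406     0.0815    0.252     0.574 1.000
#> 3 residence_urban   0.410     0.0265    0.358     0.462 1.000
#> 4 residence_rural  -0.293     0.0266   -0.346    -0.241 1.00
#> 5 sdi               0.866     0.122     0.608     1.09  1.000
#> 6 ggdph             0.0314    0.0850   -0.137     0.196 1.000
#> 7 gdpc              0.0881    0.100    -0.101     0.291 1.00
```

The generating truth (trend +0.3 logit/decade, urban +0.4, rural −0.3,
SDI +1.0) sits inside every interval, and PSRF = 1.00 signals converged
chains. `glance(fit)` adds fit-level summaries (n = 102, residual SD 0.109
against a generating τ of 0.1, DIC −148 with pD ≈ 17).

```r
proj <- predict_cci(fit, bundle$covariates, years = seq(2000, 2030, 10))
proj |> filter(unit == "C001", stratum_level != "national")
#>   unit  stratum_level  year  mean cri_low cri_high p_target
#> 1 C001  urban          2000  60.6    58.8     62.3    0
#> 2 C001  urban          2010  80.4    79.4     81.5    0.790
#> 3 C001  urban          2020  91.4    90.7     92.1    1
#> 4 C001  urban          2030  96.2    95.8     96.6    1
#> 5 C001  rural          2000  43.2    41.4     45.0    0
#> 6 C001  rural          2010  67.1    65.6     68.6    0
#> 7 C001  rural          2020  84.0    82.7     85.1    1
#> 8 C001  rural          2030  92.6    91.8     93.4    1

count_on_track(proj, year = 2030)$count   # countries with P(CCI >= 80%) >= 0.70
#> [1] 6

aggregate_region(proj) |>                 # DL meta-analysis over posterior draws
  filter(stratum_level == "national", year == 2030) |>
  select(unit, mean, cri_low, cri_high, p_target)
#>   unit   mean cri_low cri_high p_target
#> 1 R1     78.7    76.8     80.5   0.0898
#> 2 R2     65.7    62.6     68.8   0
#> 3 R3     88.6    87.4     89.6   1
```

Coverage is in percent: country C001's urban CCI rises from 60.6% (2000) to
a projected 96.2% (2030); region R3 reaches the 80% target with certainty
while R1 narrowly misses it (P = 0.09). Inequality metrics work the same
way — a wealth-quintile series with a pro-rich gradient:

```r
sii(tibble::tibble(level = paste0("Q", 1:5), cci = c(41.2, 48.9, 55.0, 61.3, 70.8)))
#>     sii scale   intercept slope
#> 1  35.8 natural      37.5  35.8
```

i.e. a slope index of inequality of 35.8 percentage points between the
extremes of the cumulative wealth ranking. See the methods vignette
(`vignettes/cci-methods.Rmd`) for the model, priors, generator design and
known limitations.

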