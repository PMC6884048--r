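# oxydose

Quantify exposure to supraphysiologic arterial oxygen (hyperoxemia) from
irregular blood-gas series and model its association with ICU mortality.

`oxydose` is aimed at critical-care epidemiologists working with routinely
collected electronic ICU records. It implements, end to end:

* **Hyperoxemia dose** — a time-weighted exposure metric. Consecutive PaO2
  samples at most 12 h apart are linearly interpolated; over an exposure
  window of `W` hours the cumulative exposure is the area above the
  13.3 kPa (100 mm Hg) threshold,

  `AUC_W = ∫ max(0, PaO2(t) − 13.3) dt` (kPa·h),  `dose = AUC_W / W` (kPa),

  with unobserved time counted as zero exposure. A dose of 1 kPa means the
  patient averaged 1 kPa above the threshold for the whole window.
* **Nested censoring-free cohorts** for windows of 24/72/120/168 h: each
  cohort keeps only episodes whose ICU stay spans the whole window, so
  exposure cannot be cut short by discharge or death.
* **Spike-at-zero outcome models** — penalized logistic regression of ICU
  mortality on the dose (linear) *and* an any-exposure indicator, plus
  covariates with restricted cubic splines for age, weight and APACHE II;
  optional exposure interactions are ridge-penalized with the penalty
  chosen by AIC over effective degrees of freedom. Probit and
  complementary log-log links are available as robustness checks.
* **Bootstrap optimism-corrected validation** (c-index, Brier score,
  calibration slope/intercept, precision–recall, AIC) and a
  **counterfactual average treatment effect** by plug-in g-computation
  (each episode's risk under observed exposure versus exposure set to 0).
* A fully specified **synthetic ICU cohort generator**, so the entire
  pipeline is testable and demonstrable without access to patient data.

## Worked example

The dose arithmetic on a two-sample series — PaO2 rising from 10 kPa at
admission to 20 kPa at 10 h crosses the threshold at 3.3 h, leaving the
triangle 6.7²/2 = 22.445 kPa·h:

```r
bg <- tibble::tibble(episode_id = "ep1", t_h = c(0, 10), pao2_kpa = c(10, 20))
compute_exposure(bg, window_h = 24)
#> # A tibble: 1 × 6
#>   episode_id window_h auc_kpa_h dose_kpa any_exposure threshold_kpa
#>   <chr>         <dbl>     <dbl>    <dbl> <lgl>                <dbl>
#> 1 ep1              24      22.4    0.935 TRUE                  13.3
```

A full synthetic study: 20,000 episodes with a true any-exposure odds
ratio of 1.5 (and no dose effect), then the complete pipeline —
exclusions, nested cohorts, one model per window, bootstrap validation
and counterfactual ATE:

```r
library(dplyr)
cfg <- cohort_config(seed = 2024,
  true_coefficients = modifyList(cohort_config()$true_coefficients,
                                 list(any_exposure = log(1.5))))
co <- simulate_cohort(cfg)
co
#> <oxy_cohort> 20000 episodes, 732976 blood-gas samples (seed 2024)

run <- run_pipeline(co$admissions, co$blood_gas, co$ventilation,
                    B = 200, seed = 2024)
run$or_summary |> filter(term == "any_exposure")
#>   window_h term         odds_ratio conf.low conf.high wald_chi2    df p.value
#> 1       24 any_exposure       1.40     1.15      1.70     11.4      1   0.001
#> 2       72 any_exposure       1.32     1.02      1.69      4.58     1   0.032
#> 3      120 any_exposure       1.38     1.02      1.87      4.36     1   0.037
#> 4      168 any_exposure       1.52     1.06      2.16      5.30     1   0.021
```

Every window's interval covers the generating odds ratio of 1.5. The
counterfactual average treatment effect (percentage points of ICU
mortality attributable to the observed exposure) grows with the window as
exposure prevalence (70.4% → 82.5%) and accumulated dose rise:

```r
purrr::map_dbl(run$ate, "ate_pp")
#>   24   72  120  168
#> 1.36 1.67 2.28 2.58

glance(run$validation[["24"]])   # optimism-corrected, B = 200
#>   c_index brier calibration_slope calibration_intercept     B B_used
#> 1   0.718  0.05             0.972                 0.002   200    200
```

`autoplot()` methods draw the calibration curve
(`autoplot(run$validation[["24"]])`) and the observed-versus-counterfactual
risk scatter with its identity line (`autoplot(run$ate[["168"]])`);
`plot_exposure()` shows one episode's samples, interpolation segments,
gaps and shaded supra-threshold area.

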