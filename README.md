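# vitdthresh

Change-point analysis of the non-linear association between serum
25-hydroxyvitamin D (25(OH)D) and urinary albumin excretion in
normoalbuminuric adults.

## The problem

Urinary albumin excretion in the *high-normal* range — a urinary
albumin-creatinine ratio (UACR) of 10-29 mg/g, below the microalbuminuria
cut-off — predicts cardiovascular disease and mortality in the general
population, and vitamin D deficiency is one of its suspected modifiable
risk factors. The relationship appears non-linear: UACR is flat across most
of the 25(OH)D range and rises only once 25(OH)D falls below a threshold.
`vitdthresh` is for epidemiologists and biostatisticians who want to
estimate that threshold and quantify the categorical association, with
every step — multi-site lab harmonization, cohort preparation, change-point
search, odds-ratio models — as tested, reusable code.

## The model at the core

For subject *i* with 25(OH)D level *D<sub>i</sub>*, response *y<sub>i</sub>*
(UACR or log-UACR) and adjustment covariates *x<sub>i</sub>*, the threshold
model is a Gaussian linear spline with one knot at the candidate threshold
τ:

> y<sub>i</sub> = x<sub>i</sub><sup>⊤</sup>β + α D<sub>i</sub> +
> δ (τ − D<sub>i</sub>)₊ + ε<sub>i</sub>,  ε<sub>i</sub> ~ N(0, σ²)

The scan refits this model for every τ on a 0.2 ng/mL grid, scores each fit
by AIC = n log(RSS/n) + 2(p + 1), and selects the τ with the lowest AIC
(all candidates share p, so this is the best-RSS knot). A no-threshold null
model is fitted alongside, and a threshold is only *reported* when the AIC
margin survives a selection-aware correction (2 log m for m candidates). A
penalized B-spline smoother (`fit_pgam()`, second-order difference penalty,
GCV-selected λ) provides the companion curve with 95% bands, and logistic
models (`category_or()`) give odds ratios for high-normal UAE across
vitamin-D categories (quartile, percentile, clinical) against the highest
category as reference.

Because cohort data of this kind are not public, the package includes a
seeded generator (`generate_cohort()`) calibrated so that 25(OH)D is
approximately N(20.4, 8.4²) ng/mL and UACR log-normal with median 4.3 mg/g
(IQR 2.5-7.7), with a configurable hockey-stick link and documented
confounding — plus a deterministic fixture reproducing the study's
exclusion arithmetic (16,870 → 14,594 records).

## Worked example

```r
library(vitdthresh)

co   <- generate_cohort(cohort_config(n_subjects = 15000), seed = 1)
prep <- apply_exclusions(co)
prep$log
#> Exclusion log
#>   input: 15000
#>   excluded (union): 144
#>     25(OH)D > 125 ng/mL: 0
#>     UACR >= 30 mg/g:     144
#>     age < 20 years:      0
#>     missing fields:      0
#>   retained: 14856

scan <- threshold_scan(prep$cohort, adjust = "full",
                       grid_low = 4, grid_high = 20, step = 0.2,
                       log_uacr = TRUE)
scan
#> AIC grid scan for the 25(OH)D change-point
#>   n = 14856, adjustment: full, response: log(UACR)
#>   grid: [4.0, 20.0] ng/mL in 0.2-steps (81 candidates)
#>   selected threshold: 7.8 ng/mL (AIC -8095.66, margin over no-threshold model 445.77)

category_or(prep$cohort, scheme = "clinical", adjust = "full")
#>           level   or ci_lo ci_hi    n n_events
#> 1    deficiency 1.51 1.282  1.77 3949      709
#> 2 insufficiency 1.03 0.884  1.20 8959     1140
#> 3   sufficiency 1.00    NA    NA 1948      233
```

Reading the output: the generator planted a change-point at 8.0 ng/mL; the
scan recovers 7.8 ng/mL (one grid step away) with an AIC margin of ~446
over the no-threshold model — overwhelming evidence for a threshold in this
cohort. In the clinical categorization, only vitamin-D deficiency
(< 15 ng/mL) carries elevated odds of high-normal albuminuria (OR 1.51,
95% CI 1.28-1.77); insufficiency is indistinguishable from the sufficient
reference — the stepwise, lowest-category-only pattern the threshold model
implies. `run_pipeline()` chains these stages (plus harmonization,
descriptive tables and probability curves) and writes CSV/JSON outputs with
a reproducibility manifest.

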