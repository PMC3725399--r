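# cytodose

Calibration of low-dose X-ray cytogenetic biomarkers: from per-cell mFISH
aberration scoring and telomere q-FISH fluorescence tables to per-endpoint
dose–response fits and detection-threshold doses with conservative 95%
upper confidence limits.

The package is aimed at radiation biodosimetry: after an exposure with no
physical dosimeter, absorbed dose must be inferred from biological
markers, and the practical question is how small a dose each marker can
report at a realistic scoring effort. `cytodose` answers it for five
mFISH endpoints — chromosome breaks, aberrant-cell fraction, stable
exchanges (balanced translocations), unstable exchanges (dicentrics,
rings, unbalanced translocations) and total aberrations — and for q-FISH
telomere T/C% ratios.

## Core model

Per-dose endpoint counts are fitted by maximum likelihood,
`y_d ~ Poisson(n_d · Y(D_d))` for per-cell yields and
`y_d ~ Binomial(n_d, F(D_d))` for the aberrant-cell fraction, with mean
functions

* linear `Y(D) = c + αD` (total aberrations),
* linear-quadratic `Y(D) = c + αD + βD²` (breaks, exchanges),
* exponential saturation `F(D) = f_max − (f_max − c)·e^(−kD)`
  (aberrant cells),
* induced-repair HRS `Y(D) = c + [α_r + (α_s − α_r)e^(−D/d_c)]·D + βD²`
  as the low-dose hyper-radiosensitivity alternative (F-tested against
  its nested LQ/linear reduction).

The **detection-threshold dose** D\* solves `Y(D*) = y_detect`, where the
minimal detectable yield `y_detect = k*/n` comes from the smallest count
`k*` in `n = 200` scored cells that a one-sided Fisher exact test flags
against the control sample at α = 0.05. Its conservative 95% upper limit
is the 95th percentile of D\* over parameter draws from the fit's
asymptotic normal, truncated to the model constraints (seeded, 10⁵ draws
by default). The methods vignette
(`vignettes/low-dose-biodosimetry.Rmd`) derives and motivates every
piece, including the calibration that fixed the criterion defaults.

## Worked example

The packaged fixture is a per-dose scoring table from AG01522 human
primary fibroblasts (500 control cells, 200 per dose at 0.1/0.25/0.5/1 Gy):

```r
library(cytodose)
tab <- table1_fixture()
fit <- fit_dose_response(tab, "breaks", "LQ")
print(fit)
#> Dose-response fit: LQ, endpoint 'breaks' (ml)
#>         estimate         se
#> c     0.05748312 0.01064066
#> alpha 0.34770675 0.11155316
#> beta  0.02126313 0.12524793
#> deviance 3.167 on 5 dose levels
```

The break yield rises from a background of 0.057/cell at ≈0.35/cell/Gy,
with negligible curvature in this dose range. The smallest break
frequency detectable over that control in a 200-cell sample is 18/200:

```r
yd <- minimal_detectable_yield(detect_criterion(control = c(26, 500)))
yd
#> [1] 0.09
threshold_dose(fit, yd)
#> [1] 0.09298933
```

so break scoring detects ≈0.09 Gy. Running the whole panel, with seeded
Monte-Carlo upper limits:

```r
thr <- threshold_table(tab)
print(thr)
#> Calculated sensitivity threshold dose [Gy] (95% upper CL)
#>   breaks               LQ: 0.09 (0.16)  [empirical 0.1 Gy]
#>   aberrant_cells       EXP_SATURATION: 0.10 (0.36)  [empirical 0.1 Gy]
#>   stable_exchanges     LQ: 0.56 (0.68)  [empirical 1 Gy]
#>   unstable_exchanges   LQ: 0.59 (0.74)  [empirical 1 Gy]
#>   total_aberrations    LINEAR: 0.10 (0.16)  [empirical 0.1 Gy]
```

Breaks, aberrant cells and total aberrations report doses around 0.1 Gy;
the exchange endpoints only 0.5–0.6 Gy — the price of the stable
exchanges' value as long-term, transmissible exposure markers. Synthetic
experiments with the same statistical structure come from `sim_config()`
+ `simulate_scoring()` / `simulate_telomeres()`, and
`run_pipeline(pipeline_config(...))` writes the full report bundle; a
thin CLI over the same functions ships in `inst/scripts/cytodose`.

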