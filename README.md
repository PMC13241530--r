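# chemocal

Multivariate calibration workflows for the simultaneous UV-spectrophotometric
quantification of two spectrally overlapped analytes — cefepime (CFPM) and
tazobactam (TAZO) — written for analytical chemists who want a reproducible,
scriptable alternative to chromatographic assays. The two drugs absorb on top
of each other below 250 nm, so no single wavelength is selective; `chemocal`
quantifies both from full spectra (210–350 nm, 141 variables) by multivariate
calibration over the ranges 1–17 µg/mL (CFPM) and 1–9 µg/mL (TAZO).

What's inside:

* **Synthetic-spectra generator** — Beer–Lambert mixtures
  `A(i, λ) = Σ_k c_ik ε_k(λ)` from a Gaussian band library, seeded
  photometric noise, optional baseline drift, and a plasma matrix model with
  known matrix factors.
* **Experimental design** — the 5-level Brereton calibration grid (25
  mixtures) and D-optimal validation-set selection (13 mixtures) by the
  Fedorov exchange algorithm, maximizing det(XᵀX) of a quadratic
  response-surface model via the classical variance-function delta rule.
* **Three calibration paradigms** sharing one fit/predict contract:
  principal component regression (SVD + leave-one-out component choice),
  firefly-optimized PLS (binary wavelength selection by a swarm with
  attractiveness β₀e^(−γr²), then NIPALS), and constrained MCR-ALS
  (evolving-factor-analysis rank, non-negativity, closure) with affine
  quantitation maps.
* **Validation statistics** — RMSE/bias/SEC/RRMSEP/BCRMSEP, net-analyte-signal
  sensitivity with LOD = 3.3 δr/SEN and LOQ = 10 δr/SEN, recovery t-tests,
  one-way ANOVA across models, elliptical joint confidence regions for
  (intercept, slope), and matrix factors ME% = (MF − 1)·100.
* **Sustainability calculators** — the per-sample carbon footprint
  CF = Σ(Pᵢ·tᵢ·EF_elec) + Σ(mⱼ·EFⱼ) and weighted aggregation of
  whiteness-style score panels.

Results come back as tibbles, models have `tidy()`/`glance()` methods, and
every result type has an `autoplot()`.

## Worked example

```r
library(chemocal)

run <- run_pipeline(chemo_config(seed = 20260605))
print(run)
```

```
chemocal pipeline run (seed 20260605 )
  calibration: 25 mixtures;  validation: 13 mixtures;  EFA rank: 2

# A tibble: 6 × 6
  model   analyte   rmsec    rmse rrmsep_standard mean_recovery
  <chr>   <chr>     <dbl>   <dbl>           <dbl>         <dbl>
1 PCR     CFPM    0.00462 0.00296          0.0327          99.9
2 PCR     TAZO    0.00677 0.00883          0.177          100.
3 FA-PLS  CFPM    0.00243 0.00646          0.0712          99.8
4 FA-PLS  TAZO    0.00470 0.0135           0.271          100.
5 MCR-ALS CFPM    0.00500 0.00434          0.0478          99.9
6 MCR-ALS TAZO    0.00806 0.00828          0.166          100.

Ranking by mean RMSEP: PCR < MCR-ALS < FA-PLS
```

Reading this: the pipeline simulated the 25-mixture Brereton calibration set
and the 13-point Fedorov validation set at 0.002 AU noise, evolving factor
analysis found the expected two-component system, and all three models
predict the external validation mixtures with relative errors (RRMSEP,
standard form) of 0.03–0.27% and mean recoveries within 0.2% of nominal —
i.e. every model is noise-limited on synthetic data. Per-model detail:

```r
v <- run$validation$`MCR-ALS`
print(v$ejcr$CFPM)
#> EJCR (95%): intercept -0.004159, slope 1, area 4.695e-06
#>   contains ideal point (0, 1): TRUE
dplyr::select(v$nas, -nas)
#> # A tibble: 2 × 5
#>   analyte   sen noise_sd    lod    loq
#> 1 CFPM    0.477  0.00190 0.0132 0.0399
#> 2 TAZO    0.275  0.00190 0.0228 0.0692
```

The joint confidence region of the predicted-vs-reference regression
contains the ideal point (0, 1), i.e. no detectable constant or proportional
bias, and the NAS detection limits are in the few-hundredths µg/mL range.
The plasma stage (`run$plasma$table`) recovers matrix factors close to the
true simulated suppression, and `run$sustainability$carbon_footprint`
evaluates the example emission inventory (0.044 kg CO₂e/sample — edit
`example_cf_inventory()` to your own factors).

The same stages are available piecemeal (`generate_brereton()`,
`fedorov_select()`, `fit_pcr()`, `fit_fapls()`, `fit_mcrals()`,
`validate_model()`, CSV readers/writers and model archives), so the pipeline
can be driven from Rscript one stage at a time, e.g.:

```sh
Rscript -e 'library(chemocal); write_conc_csv(generate_brereton(), "calib.csv")'
```

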