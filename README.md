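# cshdwi

Tumor hypoxia mapping from diffusion-weighted MRI with the
consumption-and-supply hypoxia (CSH) model, for imaging scientists who
want to apply a trained DWI hypoxia biomarker to a new cohort and for
methodologists studying how such biomarkers transfer between centers.

## What it computes

Hypoxia develops where oxygen consumption (high cellularity, read out as
low apparent diffusion coefficient, ADC) meets poor oxygen supply (low
fractional blood volume, fBV). The CSH model scores each voxel as

    s = ADC/ADC₀ + fBV/fBV₀,      ADC₀ = 0.79×10⁻³ mm²/s,  fBV₀ = 0.43

and calls it hypoxic when `s < 1`. The lesion-level biomarker HF_DWI is
the fraction of fit-valid lesion voxels classified hypoxic.

The package implements the full validation pipeline around that model:

- **`fit_voxel_segmented()` / `fit_map()`** — segmented IVIM estimation:
  log-linear OLS over b ≥ 200 s/mm² gives ADC; the b = 0 extrapolation
  gap gives fBV = 1 − S_int/S(0). Works with the 0/200/800 and
  0/50/300/800 s/mm² schemes.
- **`csh_score()`, `is_hypoxic()`, `hypoxia_level()`, `lesion_hf()`** —
  voxel classification and lesion hypoxia fractions.
- **`match_cohorts()`, `compute_scaling_factors()`, `apply_scaling()`** —
  cross-center calibration: propensity-score optimal 1:1 matching on pGG
  and pTstage (reference cohort kept whole), then median scaling
  F_ADC = median ADC(ref)/median ADC(target) (likewise F_fBV) applied to
  the target voxels.
- **`compare_groups()`, `kruskal_wallis_by_grade()`,
  `pearson_hf_vs_grade()`** — assumption-gated two-sample tests
  (Shapiro-Wilk + Levene gate choosing t-test vs Mann-Whitney),
  grade-wise Kruskal-Wallis and the HF-grade correlation.
- **`sample_cohort()`, `forward_dwi()`** — a synthetic two-center cohort
  generator (grade-dependent joint (ADC, fBV) distributions, IVIM forward
  signals, Rician noise, center biases) so the whole pipeline is testable
  without patient data.
- **`run_all()`** — the end-to-end orchestration:
  simulate → fit → match → calibrate → HF → statistics, deterministic
  from one seed.

NIfTI volumes are read and written with RNifti (`read_dwi()`,
`read_lesion_mask()`, `write_param_map()`); cohort metadata, per-lesion
results and voxel pools travel as plain CSV.

## Worked example

```r
library(cshdwi)
res <- run_all(pipeline_config(seed = 7))
print(res)
```

```
CSH validation pipeline (seed 7)
Scaling factors: F_ADC = 0.8247, F_fBV = 1.4729
[reference]
pGG_low_vs_high: mann_whitney, statistic = 128, p = 8.48e-16
  medians: pGG<3 = 0.103, pGG>=3 = 0.284
pTstage_2_vs_3: mann_whitney, statistic = 737, p = 0.000193
  medians: pTstage=2 = 0.128, pTstage=3 = 0.235
[target]
pGG_low_vs_high: mann_whitney, statistic = 188, p = 1.76e-14
  medians: pGG<3 = 0.126, pGG>=3 = 0.273
pTstage_2_vs_3: mann_whitney, statistic = 750, p = 0.00027
  medians: pTstage=2 = 0.141, pTstage=3 = 0.222
```

Reading this: the simulated target center acquires ADC values ~20% high
and fBV values ~35% low relative to the reference; the estimated scaling
factors (0.82, 1.47) undo most of that bias. After calibration, both
cohorts show the same clinical pattern — median lesion hypoxia fraction
roughly 0.10-0.13 in low-grade (pGG < 3) disease versus 0.27-0.28 in
high-grade, and higher HF in stage-3 tumors — and the gated tests flag
both associations. The full-target-cohort grade correlation is available
as `res$stats$target$pearson`:

```
rho = 0.74 (n = 327, p = 1.31e-58)
```

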