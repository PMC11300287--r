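---
title: "Consumption-and-supply hypoxia mapping from DWI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumption-and-supply hypoxia mapping from DWI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cshdwi)
```

## The model

Tumor hypoxia arises when oxygen consumption outstrips supply. In
diffusion-weighted MRI (DWI), the apparent diffusion coefficient (ADC)
falls with cellular density — a proxy for oxygen *consumption* — while the
fractional blood volume (fBV), the perfusion fraction of the baseline DWI
signal, is a proxy for oxygen *supply*. The consumption-and-supply hypoxia
(CSH) model classifies a voxel as hypoxic when it is simultaneously low in
both, i.e. when it falls strictly below the line

$$\frac{\mathrm{ADC}}{\mathrm{ADC}_0} + \frac{\mathrm{fBV}}{\mathrm{fBV}_0} < 1,$$

with intercepts $\mathrm{ADC}_0 = 0.79 \times 10^{-3}\,\mathrm{mm^2/s}$ and
$\mathrm{fBV}_0 = 0.43$ (trained once against pimonidazole staining in the
original cohort, and treated as frozen constants here — `csh_params()`
exposes them but this package never refits them). The lesion-level
biomarker is the hypoxia fraction `HF_DWI`: the fraction of a lesion's
fit-valid voxels classified hypoxic. A per-voxel hypoxia level
$\mathrm{HL} = \max(0, 1 - s)$, the clipped deficit of the score $s$, is
exported for visualization only; no statistic consumes it.

Two conventions were genuinely open and are fixed as follows. Boundary
voxels ($s = 1$ exactly) are *non-hypoxic*: the boundary has measure zero
on continuous data, and strictness makes small worked examples
unambiguous. HF denominators count only voxels with a *valid* segmented
fit: a lesion with zero valid voxels raises an error rather than reporting
HF = 0, because "no evidence" and "no hypoxia" must not be conflated.

## Segmented IVIM estimation

The intravoxel incoherent motion (IVIM) signal model is bi-exponential:
capillary pseudo-diffusion ($D^*$, of order $10 \times 10^{-3}$ mm²/s)
decays an order of magnitude faster than tissue diffusion. The segmented
approach (`fit_voxel_segmented()`, `fit_map()`) never estimates $D^*$:

1. For all $b \ge b_{\mathrm{thr}}$ (default 200 s/mm², inclusive),
   ordinary least squares of $\log S(b)$ on $b$ gives ADC as the negative
   slope and the extrapolated intercept $S_{\mathrm{int}}$.
2. $\mathrm{fBV} = 1 - S_{\mathrm{int}} / S(0)$.

With the two acquisition schemes supported by default, $\{0, 200, 800\}$
and $\{0, 50, 300, 800\}$ s/mm², the threshold of 200 (the conventional
perfusion-suppression cutoff) leaves exactly the $\ge 2$ high-b points a
log-linear fit needs; with only two points nonlinear least squares would be
overparameterized, so OLS on the log scale is used throughout. ADC is
clamped to $[0, 4 \times 10^{-3}]$ mm²/s and fBV to $[0, 1]$: small
negative fitted fBV under noise is clamped rather than rejected so that HF
denominators keep their voxels, while genuinely unusable voxels
($S(0) \le 0$, any non-positive high-b sample, or fewer than 2 high-b
samples) are marked invalid and excluded from every downstream median and
HF. On noise-free single-exponential signals the estimator is exact to
floating-point precision (the test suite verifies $10^{-9}$ relative over
a grid of $D$ and $f$); on true bi-exponential signals the residual
perfusion above the threshold produces a small, analytically predictable
downward leakage bias in fBV, which the tests compute from the forward
model rather than assume away.

## Cross-cohort calibration

Quantitative ADC/fBV values shift between centers (vendor, sequence and
analysis differences), so the discrimination line cannot be transferred
naively. The calibration exploits an exact invariance: the CSH score is
unchanged when values and intercepts are rescaled together, so multiplying
target-cohort voxels by

$$F_{\mathrm{ADC}} = \frac{\mathrm{median\,ADC(reference)}}{\mathrm{median\,ADC(target)}},
\qquad
F_{\mathrm{fBV}} = \frac{\mathrm{median\,fBV(reference)}}{\mathrm{median\,fBV(target)}}$$

aligns the pooled distributions (medians become equal exactly, a property
of the median under positive scaling) and lets the published intercepts be
reused. Medians are computed on voxels pooled over *all lesions* of the
matched cohorts, not on per-lesion medians. The target cohort is the only
one ever rescaled.

To prevent case-mix differences from masquerading as scanner effects, the
cohorts are first matched on pathology: a logistic propensity model of
target-cohort membership on indicator-coded pGG (five levels) and pTstage
(two levels), then optimal 1:1 matching on the logit scale under the
"average treatment effect on the control" estimand — every reference
patient is retained, only target patients may be dropped, no caliper.
Indicator coding (rather than linear scores) lets optimal matching achieve
exact stratum matching whenever counts permit, which is what the balance
diagnostics (standardized mean differences before/after) verify. Because
the propensity logit is one-dimensional and the cost is an absolute
difference, an optimal non-crossing assignment exists in sorted order;
`optimal_match()` therefore solves the assignment by an $O(nm)$ dynamic
program over the two sorted cohorts, which the tests check against
exhaustive enumeration on all small instances. If some covariate stratum
occurs in only one cohort, the logistic fit is separable; the model then
falls back to empirical stratum proportions (the saturated-fit limit) with
a warning.

## Group statistics

Comparisons of HF between low (pGG < 3) and high (pGG ≥ 3) grade and
between pTstage 2 and 3 use an assumption gate: a pooled-variance t-test
only if both groups pass Shapiro-Wilk normality *and* mean-centered
Levene homogeneity at $\alpha = 0.05$; otherwise Mann-Whitney. All tests
are two-sided, without multiplicity correction. One consequence of the
conjunction rule worth stating: even on perfectly normal data the t-branch
is selected only about $0.95^3 \approx 86\%$ of the time, since each gate
spends its own type-I error. The gated procedure's overall type-I error
stays near nominal (the suite verifies the 1000-replicate rejection rate
lies in $[0.01, 0.10]$ at nominal 0.05), because both branches are valid
level-$\alpha$ tests under the null.

The grade-wise analysis uses tie-corrected Kruskal-Wallis across pGG 1-5
and Pearson correlation of HF against the integer grade codes (Spearman is
available as an option but is not the default). Per-patient analyses use
the index lesion (highest pGG, ties broken by lowest lesion id); the
full-cohort grade analysis is per-lesion.

## The synthetic cohort generator

`sample_cohort()` emulates the structure the analysis assumes, so the
whole pipeline is testable without patient data:

- **Demographics.** Grade-group frequencies default to 8/44/26/16/12 per
  106 patients; pTstage 3 probability rises with grade as
  (0.25, 0.50, 0.75, 0.85, 0.90), whose weighted mean reproduces the
  overall 68/106 stage-3 fraction. The target-cohort default in
  `pipeline_config()` instead uses the larger, low-grade-skewed mix
  (291 patients, 45/147/76/30/21 grade weights per 319 lesions, ~10% of
  patients with a second lesion), so matching has a real subset to select.
- **Voxels.** Lesions of 50-2000 voxels (log-uniform). Each lesion draws a
  latent hypoxia factor (between-lesion SD 0.6) centered on a per-grade
  shift; each voxel adds unit-SD noise to it. The factor moves ADC
  (truncated normal, center $0.70 \times 10^{-3}$ mm²/s, SD
  $0.12 \times 10^{-3}$, truncation $[0.1, 3.0] \times 10^{-3}$) and the
  fBV Beta mean (base 0.125, concentration 20, logit slope 0.2) jointly
  downward, inducing the correlated low-ADC/low-fBV tail the CSH score
  reads as hypoxia. True lesion HF is therefore *emergent*: it is
  recomputed from the stored voxels under the published intercepts, never
  sampled directly. The per-grade centers are deliberately grade-constant,
  so zeroing the shifts yields an exchangeable no-signal cohort — a
  property the tests use as a null construction.
- **Calibration of the defaults.** The five grade shifts
  (−2.127, −1.129, −0.216, 0.323, 0.692) were solved by root-finding so
  the median-latent lesion of each grade lands on per-grade HF targets
  (0.045, 0.112, 0.215, 0.295, 0.355), chosen to reproduce the published
  group medians (≈0.11 for pGG < 3, ≈0.27 for pGG ≥ 3) with pooled voxel
  medians near ADC $0.70 \times 10^{-3}$ mm²/s and fBV 0.125. The voxel
  spreads are tighter than the published cohort IQRs: with the published
  pooled medians the median CSH score is ≈1.17, and IQR-matched spreads
  would force the low-grade HF toward 0.3, contradicting the published
  0.11 — medians and HF levels were prioritized. A consequence is that the
  simulated HF-grade correlation (ρ ≈ 0.7-0.8) is stronger than on real
  data (≈0.4); tests therefore assert direction and significance of the
  association, not its exact magnitude.
- **Signals.** Forward IVIM signals in two modes: *ideal* (perfusion
  contributes only at b = 0; the segmented fit inverts it exactly, giving
  the noise-free loop-closure tests) and *bi-exponential* with
  $D^* = 10 \times 10^{-3}$ mm²/s. Noise is Rician,
  $S' = \sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with
  $\epsilon \sim N(0, (\sigma S_0)^2)$ and $\sigma = 0.02$ (SNR 50 at
  b = 0) — Rician rather than Gaussian because the magnitude-noise floor
  is a genuine failure mode for fBV estimation. Background voxels carry
  pure noise (the Rayleigh floor $\sigma S_0 \sqrt{\pi/2}$).
- **Center bias.** Multiplicative biases on ADC and fBV are applied after
  the truth (and true HF) is stored, before signal generation. The default
  target biases (1/0.83, 1/1.54) are the inverses of the published scaling
  factors, so the simulated inter-center shift is the one the calibration
  is expected to undo.

What the generator does *not* emulate: anatomy (lesions are packed into
compact grids, not prostate-shaped), partial-volume and distortion
artifacts, T2w/high-b delineation series, spatial voxel correlation within
lesions, and realistic ADC/fBV IQRs (see above). Passing tests show the
*pipeline machinery* is correct under the stated generative assumptions;
they are not evidence about real scanners.

## Determinism and numerical choices

Everything flows from one seed: `run_all()` derives per-stage seeds from
the master seed, and reruns are byte-identical (tested on the emitted CSV
and JSON artifacts). The voxelwise OLS is computed with `rowSums` rather
than BLAS matrix products so that identical voxels give bit-identical
estimates regardless of vectorization kernels. Assignment ties in the
matcher are broken deterministically by (value, patient id) sort order.
Truncated-normal draws use inverse-CDF sampling so marginals are exact.
Scaling re-clamps fBV to $[0, 1]$ and reports the clamp count.

## Problem sizes

The shipped test suite and acceptance script run at the study's own scale
where that is cheap (106 + 291 patients, ~530 voxels per lesion on
average; the full pipeline takes a few seconds) and at reduced scale for
the exactness properties (e.g. 12-25 patients for noise-free loop-closure
tests, which are scale-invariant by construction). Stochastic checks use
1000 replicates for type-I error, 50 for power, 100-200 for the remaining
frequency assertions, each under a fixed seed.

## Known limitations

- The intercepts are constants taken from the original training; nothing
  here validates them against histology.
- Median scaling aligns location only; shape differences between cohorts
  (e.g. different IQRs) are untouched, and no ComBat-style harmonization
  is attempted.
- The segmented estimator's fBV carries the $D^*$ leakage bias on truly
  bi-exponential signals; it is small at the default $D^*$ but systematic.
- Pearson on ordinal grade codes treats grade steps as equidistant; the
  Spearman option relaxes this.
- In the generator, stage is linked to hypoxia only through its
  correlation with grade, so the simulated pTstage effect is weaker than
  the grade effect and can be non-significant (or even inverted in the
  medians) at individual seeds, unlike the grade effect, which is the
  directly calibrated signal.
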