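---
title: "APT and ASL histogram biomarkers for stroke outcome prognosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{APT and ASL histogram biomarkers for stroke outcome prognosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptasl)
```

This vignette documents the science and the engineering decisions behind
`aptasl`: the quantification models and their assumptions, the parameters
that matter and their defaults, what the synthetic generator does and does
not emulate, the numerical conventions, and the genuinely open design
choices and how they were resolved. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The pipeline and its clinical setting

In subacute ischemic stroke treated with intravenous thrombolysis, lesion
tissue differs from healthy contralateral tissue in two measurable ways:
its perfusion (restored, or not, by reperfusion) and its pH (depressed by
anaerobic lactate accumulation). ASL quantifies the former as cerebral
blood flow; APT-weighted CEST imaging is sensitive to the latter because
the amide proton exchange rate is base-catalyzed. The pipeline turns one
subject's raw volumes into 20 relative biomarkers — ten first-order
histogram statistics per map, differenced lesion minus contralateral
(rAPT, rASL) — and a cohort of such rows into a prognostic report:
Mann–Whitney screening, cross-validated LASSO selection, a logistic
combination, and ROC operating characteristics separating favorable
(mRS 0–2) from unfavorable (mRS 3–6) outcomes.

## 2. Quantification models

### 2.1 APT: MTR asymmetry

The APT-weighted signal is the magnetization transfer ratio asymmetry at
3.5 ppm,
$$\mathrm{MTR_{asym}}(3.5\,\mathrm{ppm}) =
  \frac{s(-3.5\,\mathrm{ppm}) - s(+3.5\,\mathrm{ppm})}{s_0},$$
computed voxelwise from exactly two saturated images and the unsaturated
reference. Assumptions worth stating:

- **No B0 correction, no Z-spectrum interpolation.** The modelled
  acquisition measures only the two ±3.5 ppm offsets plus $s_0$, so there
  is nothing to fit; `compute_mtrasym_map()` accepts a pre-corrected stack
  if the scanner pipeline provides one.
- **No multi-pool modelling.** Aliphatic NOE and semisolid MT effects
  contaminate the asymmetry in vivo; separating them (Lorentzian fitting)
  is out of scope.
- **Invalid voxels are flagged, not imputed.** Voxels with $s_0 \le 0$ or
  non-finite inputs carry `NA` and a `FALSE` validity flag, and are
  excluded from every downstream histogram.
- **Single-slice APT.** The APT acquisition is a single 2D slice placed at
  the lesion's maximum extent; `lesion_max_slice()` reproduces that choice
  as the slice with the largest lesion-mask area (ties to the lowest
  index), and `subject_relative_features()` computes rAPT on that slice
  only while rASL uses the full 3D masks.

The map is a dimensionless fraction internally; conversion to percent
happens once, in `relative_features_row()`, because the reported rAPT
biomarkers are conventionally in percent.

### 2.2 ASL: single-compartment pCASL

CBF is quantified from the control/label difference $\Delta M$ as
$$\mathrm{CBF} = k \cdot
  \frac{\Delta M \; e^{w/T_{1a}} \; e^{TE/T_{2a}}}
       {\rho \cdot 2\alpha \, T_{1a} \, M_{0a}},
  \qquad
  M_{0a} = \frac{S_{csf}}{\lambda_a \left(1 - e^{-TR/T_{1csf}}\right)}.$$

Two points deserve flags:

- **Equation grouping.** The source description of this model is typeset
  ambiguously; the grouping implemented — decay terms in the numerator over
  the $\rho\,2\alpha T_{1a} M_{0a}$ denominator — is the standard
  single-compartment single-PLD quantification, chosen for dimensional
  consistency. The CSF calibration is likewise the standard
  saturation-recovery form (it reduces to $S_{csf}/\lambda_a$ as
  $TR \to \infty$).
- **Bolus term.** Consensus models include a labeling-duration factor
  $(1 - e^{-\tau/T_{1a}})$. The modelled analysis does not print it, so it
  is off by default and available as `include_bolus_term = TRUE`. With the
  default constants it rescales CBF by ≈ 1/0.664, so the choice matters
  for absolute values — but not for lesion-minus-contralateral differences
  of the kind this pipeline feeds into statistics, which scale uniformly.

Negative $\Delta M$ yields negative CBF and is retained: relative
biomarkers are signed, and hypoperfused-minus-normal differences are
exactly the negative values that carry prognostic signal.

Parameter defaults (all overridable in `asl_quant_params()`):

| parameter | default | unit | origin |
|---|---|---|---|
| w (post-labeling delay) | 2000 | ms | acquisition protocol |
| TE | 13.58 | ms | acquisition protocol |
| TR | 5500 | ms | acquisition protocol |
| labeling duration τ | 1800 | ms | protocol; used only by the bolus term |
| T1a | 1650 | ms | 3T arterial blood literature value |
| T2a | 150 | ms | 3T arterial blood literature value |
| α (labeling efficiency) | 0.85 | — | standard pCASL value |
| ρ (tissue density) | 1.0 | g/mL | convention |
| λa (blood water volume) | 0.76 | — | stated calibration constant |
| T1csf | 4300 | ms | 3T CSF literature value |
| k (unit scale) | 6000 | — | s→min and g→100 g |

The physiological constants (T1a, T2a, α, ρ, T1csf) are not printed by the
modelled protocol; the defaults are the values a 3T pCASL analysis would
use, and configurability preserves fidelity to whatever a scanner actually
assumed. Times are entered in ms and converted to seconds internally so
that `unit_scale = 6000` has its conventional meaning.

## 3. ROIs, resampling and histogram features

The lesion ROI lives on the DWI grid; APT and CBF maps are lower
resolution. `resample_to_reference()` assumes the affine alignment is
given (identity for phantoms — deformable registration is out of scope)
and interpolates with nearest-neighbour or trilinear weights. Validity
propagates *conservatively*: a resampled voxel is valid only if every
source voxel with nonzero interpolation weight is valid and in bounds.
This loses a rim of voxels at mask edges but never launders an invalid
value into a statistic.

The contralateral ROI is the left–right mirror of the lesion mask
(`mirror_mask()`), the automated counterpart of drawing a control region
on the opposite hemisphere. Mirroring is exact reflection about the array
midplane; it preserves voxel count and is an involution. Necrotic,
hemorrhagic or cystic regions that a radiologist would exclude are the
caller's responsibility via the mask (no automatic detection).

Histogram conventions, isolated in `extract_histogram_features()` because
software differs and the choice is otherwise invisible:

- percentiles by linear interpolation at position $(n-1)q$ of the sorted
  sample (R's type 7, the most common default in scientific software);
- skewness $m_3/m_2^{3/2}$, kurtosis as *excess* kurtosis
  $m_4/m_2^2 - 3$ — chosen because published group means for kurtosis
  straddle zero, which identifies the excess convention;
- a zero-variance ROI reports skewness = kurtosis = 0 with a `degenerate`
  flag rather than NaN.

Relative features subtract at the statistic level
($r_{\max} = \max_{lesion} - \max_{contra}$), not over a voxelwise
difference image, because the two ROIs need not have equal voxel counts.

## 4. The statistical tail

- **Screening.** Two-sided Mann–Whitney per feature at α = 0.05, no
  multiplicity correction (matching the modelled analysis). The p-value is
  exact by full enumeration when $n_1 + n_2 \le 16$ with no ties
  (dynamic-programming count of the null distribution of U, verified
  against brute-force `combn` enumeration and `wilcox.test`), otherwise a
  normal approximation with tie and continuity corrections. At
  $n_1 = n_2 = 8$ the approximation deviates from the exact p by at most
  0.0109 (computable by enumeration), which is the bound the property test
  asserts. A constant feature reports p = 1.
- **Selection.** LASSO-penalized logistic regression (glmnet) on
  standardized features, λ chosen by 10-fold cross-validated binomial
  deviance on outcome-stratified folds; fold assignment derives from the
  single analysis seed. The default candidate set is the
  screened-significant features — the screen-then-select order — with
  `lasso_on = "all"` available. The λ rule is minimum mean CV deviance
  (`"1se"` available). If LASSO zeroes everything, the screened set is
  carried forward so a combination is still reportable. Note the LASSO
  active set is not strictly monotone in λ: coordinate-descent paths can
  transiently drop and re-admit a variable at a knot, so the monotonicity
  property is asserted only up to a unit wiggle.
- **Combination.** Maximum-likelihood logistic regression of
  unfavorable = 1 on the selected features; the combined score is the
  linear predictor. Complete separation — common at n = 58 with several
  strong markers — makes the MLE diverge, so it is detected and raised as
  an error by default; `ridge_epsilon > 0` opts into a lightly penalized
  fit instead. The acceptance runs use `ridge_epsilon = 0.01`, declared up
  front as part of the analysis configuration.
- **ROC.** AUC by the rank/pair-counting identity with ties counted one
  half (so AUC = U/(n₁n₂) exactly, a cross-operation identity the tests
  assert); SE by the DeLong placement-variance estimator; 95% CI on the
  logit scale, truncated Wald at the boundary; operating cutoff by the
  Youden index (the named analysis software's default), with
  closest-to-(0,1) as an alternative. If the raw AUC is below 0.5 the
  orientation flips and is recorded; `auc_raw` keeps the unoriented value.
- **Permutation control.** The label-permutation null check uses the raw
  AUC of the *fixed* fitted score against shuffled labels, which averages
  0.5 exactly under the null. Refitting the model per permutation would
  not: an in-sample refit on ~58 subjects with several covariates is
  optimistically biased by roughly +0.1 AUC, and the AUC ≥ 0.5
  orientation rule alone folds the null mean to ≈ 0.57. A calibration
  band of 0.5 ± 0.03 is only meaningful for the fixed-score control, so
  that is what `permutation_auc_control()` implements.
- **Evaluation is apparent (in-sample).** The modelled analysis reports no
  held-out validation, and neither does this package; the reported AUCs
  are optimistic estimates of generalization, which is precisely why the
  permutation control matters.

## 5. The synthetic world

The generator has two levels, and its defaults are a *stated world* — they
were chosen once, for realism, and are not tuned against test outcomes.

**Image-level phantoms** (`phantom_spec()`,
`generate_phantom_subject()`): a spherical lesion (radius 10 mm) in the
left half of a 48×48×12 grid at 2×2×6 mm, background MTRasym 0 vs lesion
0.03 (a 3% asymmetry, the order seen in brain tissue), background CBF 40
vs lesion 60 mL/100 g/min (normal gray-matter-ish perfusion vs moderate
hyperperfusion after recanalization). Raw signals are constructed by
algebraically inverting the quantification equations — $s_0 = 1000$ a.u.,
50% baseline saturation split antisymmetrically by the programmed
MTRasym; ASL control at 500 a.u. with the label offset by the ΔM that the
CBF equation demands (≈ 2% of the control signal, a realistic ASL
difference), $S_{csf} = 760$ a.u. Gaussian noise (default SD 1% of $s_0$,
i.e. SNR ≈ 100) is added to the *raw* signals, because acquisition noise
enters before quantification, not on derived maps. Noiseless phantoms
therefore round-trip exactly (the tests demand 1e−6 relative), and every
random draw flows from one integer seed through a per-subject counter, so
cohorts are reproducible regardless of generation order.

What the phantoms deliberately do not emulate: brain anatomy,
partial-volume effects, B0/B1 inhomogeneity, motion, the NOE/MT
contamination of real Z-spectra. A green round-trip test establishes that
the quantification inverts its own forward model — not that the forward
model captures a scanner.

**Feature-level cohorts** (`generate_feature_cohort()`): 20 features per
subject drawn as independent Gaussians with group-specific means and SDs,
defaulting to the published group summaries of the modelled 58-patient
cohort (18 favorable / 40 unfavorable; e.g. rASL mean 27.45 ± 36.55 vs
−7.86 ± 39.8 mL/100 g/min). Published tables carry no covariance
information, so independence is the default and an equicorrelation within
each 10-feature family is configurable. Real histogram features of one ROI
are strongly mutually correlated; a green structure-recovery test
therefore establishes power under independence, not under realistic
correlation. One labeling ambiguity in the source tables (columns headed
"mRS < 2 / mRS ≥ 2" against an otherwise consistent 0–2 vs 3–6 split) is
resolved in favor of the 0–2/3–6 split with the published group sizes.

## 6. Numerical and degenerate-input choices

- Percentile, skewness and kurtosis conventions: §3 above; all isolated in
  one function.
- MTRasym validity: $s_0 \le 0$ voxels are invalid, never divided through.
- MWU with zero rank variance (fully tied data): p = 1.
- ROC with AUC on the boundary (0 or 1): Wald CI truncated to [0, 1]
  instead of the undefined logit form.
- Youden ties: the smallest threshold among maximizers (thresholds are
  scanned in increasing order and `which.max` takes the first).
- Separation in the logistic fit: error by default, opt-in ridge; a
  single-feature ridge fit pads an inert zero column because the backend
  requires two.
- Resampling at the exact upper grid edge: clamped into the last cell so a
  reference grid that exactly tiles the source stays in bounds.
- Seeds: one integer seed per public entry point, expanded via a
  multiplicative counter stream (`derive_seed()`), all below 2³¹.

## 7. Known limitations

- The NIfTI layer is minimal on purpose (uncompressed `.nii`, 2–4D,
  float/int types, sform affine); it exists because the deployment
  environment provides no NIfTI reader, and it is cross-validated against
  an independent reader (nibabel) in the tests. No `.nii.gz`, quaternions,
  or extensions.
- Registration is reduced to affine resampling with a supplied transform;
  estimating the transform (e.g. with FSL) is outside the package.
- The ROC evaluation is apparent; the optional optimism machinery
  (bootstrap) was considered and dropped as out of scope.
- Published headline performance (combination AUC ≈ 0.97 on 58 patients)
  is not reproducible from synthetic data and is not claimed; the tests
  verify internal correctness, calibration, and distribution-level
  structure recovery instead.
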