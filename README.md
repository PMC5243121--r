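# dcelbv

Identifying poorly perfused tumor subvolumes from DCE-MRI temporal
features.

## The problem

In dynamic contrast-enhanced MRI (DCE-MRI), a T1-weighted volume is
acquired every few seconds during a contrast-agent bolus, giving every
tumor voxel a signal–time curve. Tumor subvolumes with **low blood
volume (LBV)** — poorly perfused, presumably hypoxic and radioresistant
tissue — are of direct interest in radiotherapy of head-and-neck cancer:
large persistent low-BV subvolumes predict local and regional failure and
are candidate targets for dose intensification. The conventional route to
a blood-volume map is voxelwise pharmacokinetic (PK) fitting of the
two-compartment Tofts model

&nbsp;&nbsp;&nbsp;&nbsp;*C<sub>t</sub>(t) = v<sub>p</sub> C<sub>p</sub>(t) + K<sup>trans</sup> ∫₀ᵗ C<sub>p</sub>(τ) e<sup>−k<sub>ep</sub>(t−τ)</sup> dτ*,

followed by thresholding the derived BV map (BV < 7.6 % ⇒ low BV). This
two-step analysis is slow and initialization-sensitive. `dcelbv`
implements the alternative: classify each voxel **directly from temporal
features of its enhancement curve**, with PK modeling used only to label
the training data.

The pipeline:

1. **Preprocess** — each curve is converted to relative enhancement
   ΔS(t) = (S(t) − S₀)/S₀, normalized by the peak enhancement of the
   arterial input function (AIF), and windowed to 32 time points starting
   at the AIF onset (ΔS_N(t) = ΔS(t)/AIF_max).
2. **Features** — either the full 32-coefficient Haar wavelet
   decomposition [A₅, D₅, …, D₁] (A₅ ∝ area under the curve), or
   projections onto principal components of the training curves.
3. **Select** — correlation-based feature-subset selection (Hall's CFS
   merit *M = k r̄<sub>cf</sub> / √(k + k(k−1) r̄<sub>ff</sub>)* with
   best-first or greedy forward search) for wavelet features; the leading
   *k* = 4 components for PCA features.
4. **Classify** — a soft-margin RBF-kernel SVM (C = 200, γ = 0.2) with
   Platt-calibrated posterior probabilities; a voxel is low-BV when
   P(low BV) > 0.5.
5. **Assemble** — classified low-BV voxels are grouped into connected
   components and components smaller than 1 cc are excluded; the result
   is compared with the PK-derived reference by voxel accuracy and the
   Dice similarity coefficient DSC(G, R) = 2|G∩R|/(|G|+|R|).

Since clinical DCE data cannot ship with a package, `dcelbv` includes a
seeded **digital phantom**: a 4D series whose tumor voxels follow the
Tofts model with known voxelwise (v<sub>p</sub>, K<sup>trans</sup>,
k<sub>ep</sub>), an analytic AIF carried by an artery region, and
Gaussian noise — so every stage can be validated closed-loop against
ground truth, including cross-dialect robustness (7.7 s ↔ 3 s temporal
resolution) and AIF-perturbation sensitivity experiments.

## Worked example

```r
library(dcelbv)

cfg     <- acquisition_config(noise_sd_rel = 0.05, seed = 17)  # 60 frames @ 3 s
phantom <- generate_phantom(cfg)
phantom
#> <dce_phantom> 40 x 40 x 16 grid, 60 frames at 3 s
#>   tumor voxels: 3045 (low-BV fraction 0.211)
#>   artery voxels: 36, noise SD (rel. to S0): 0.05

report <- run_pipeline(phantom, mode = "pca")
report
#> <dce_report> mode = pca, 3045 voxels (2132 train / 913 test)
#>   held-out accuracy: 99.3%   DSC (s-LBV): 0.996   DSC (LBV+HBV): 0.999

tidy(report$classifier$basis)[1:2, ]
#> # A tibble: 2 x 4
#>   component   sdev var_explained cum_var_explained
#> 1         1 0.353         0.868              0.868
#> 2         2 0.0874        0.0531             0.921

run_pipeline(phantom, mode = "wt")
#> <dce_report> mode = wt, 3045 voxels (2132 train / 913 test)
#>   held-out accuracy: 98.4%   DSC (s-LBV): 0.985   DSC (LBV+HBV): 0.996
#>   selected coefficients: 1, 2, 9, 17
```

The phantom's 3045 tumor voxels contain two embedded low-BV lesions
(21 % of the tumor). Both feature sets classify held-out voxels with
~98–99 % accuracy and recover the low-BV subvolume with DSC ≈ 0.99
(≥ 0.7 is conventionally "excellent" overlap). The wavelet search selects
the approximation coefficient A₅ (index 1, global curve area), the
coarsest detail D₅ (index 2) and the earliest-time detail of two finer
scales (indices 9, 17) — global shape plus early-enhancement slope. The
first principal component alone explains ~87 % of the curve variance.

`autoplot(report)` draws the posterior-probability map with the retained
subvolume outlined; `plot_curves()` and `plot_sensitivity()` cover the
other result types. A command-line front end with verbs `simulate`,
`fit-bv`, `train`, `predict`, `evaluate` and `sensitivity` is installed
at `system.file("cli/dcelbv", package = "dcelbv")`.

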