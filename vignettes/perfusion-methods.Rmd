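---
title: "Quantifying tumor perfusion: models, phantom, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor perfusion: models, phantom, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorperf)
```

## Why measure tumor perfusion

Angiogenesis drives tumor growth, and antiangiogenic drugs act first on the
vasculature — often days before any change in tumor volume. Tissue blood
flow is therefore an attractive early-response biomarker. `tumorperf`
implements the two MRI readouts used for this purpose in small-animal
xenograft studies, together with the supporting quantification, QC, and
statistics:

* **FAIR arterial spin labeling (ASL)**: magnetically labeled arterial
  water serves as an endogenous, fully diffusible tracer, yielding absolute
  blood flow in mL/100 g/min.
* **Semi-quantitative DCE-MRI**: bolus arrival time, time of maximum
  enhancement, and the initial area under the enhancement curve (AUC60/90/
  150), chosen over pharmacokinetic modeling because the semi-quantitative
  parameters are substantially more reproducible.

Because no public raw data exist for this kind of acquisition, the package
ships a digital tumor phantom with known ground truth, and every stage of
the analysis is validated against it.

## The FAIR kinetic model

FAIR alternates a nonselective (global) inversion with a slice-selective
inversion. In the slice-selective ("label") condition, inflowing blood is
fresh; in the global ("control") condition it is inverted like the static
tissue. The difference per inversion time TI,

$$\Delta M(TI) = 2 M_0 \alpha \frac{f}{\lambda}
  \frac{e^{-TI/T_{1app}} - e^{-TI/T_{1a}}}{1/T_{1a} - 1/T_{1app}},$$

is the zero-transit-time solution of the general kinetic model. At
`t1app == t1a` the expression has a removable singularity; the package
evaluates the limit $2 M_0 \alpha (f/\lambda)\,TI\,e^{-TI/T_{1a}}$ there
(`fair_delta_m_model()` switches branches when the relaxation rates agree
to within one part in 10^9^). Transit time is fixed at zero: for a thin
imaging slice inside a much wider inversion slab, spin delivery is
effectively instantaneous.

Constants (`asl_constants()`), with their conventional values at 7 T:

| parameter | meaning | default | units |
|---|---|---|---|
| `lambda_part` | blood/tissue water partition coefficient | 0.9 | mL/g |
| `t1a` | arterial blood T1 | 2210 | ms |
| `alpha` | inversion efficiency | 1.0 | — |
| `transit_time` | arterial transit delay | 0 | ms |

Flow is stored and reported in mL/100 g/min and converted internally to
1/ms via $f/(6000\,\lambda \cdot 1000)$ wherever it combines with
relaxation rates.

The perfusion-dependent apparent relaxation is
$1/T_{1app} = 1/T_1 + f/\lambda$ (`t1app_from_t1()`). Following the
acquisition design — the inversion-recovery T1-mapping series is acquired
at the ASL slice with slice-selective-like recovery — the T1 fitted from
that series is treated as $T_{1app}$ directly and passed to the flow fit,
rather than reconstructing $T_{1app}$ from a separately measured $T_1$
and the (unknown) flow.

### The single-parameter flow fit

With $M_0$ and $T_{1app}$ fixed per voxel by the T1 fit, $\Delta M(TI)$ is
*exactly linear* in the one free parameter $f$. The least-squares problem
per voxel therefore has the closed-form solution
$\hat f = \sum_i g(TI_i)\,\Delta M_i \,/\, \sum_i g(TI_i)^2$ with $g$ the
model at unit flow; `fit_perfusion()` computes this projection rather than
iterating, which is both exact and fast. Negative estimates are clamped at
zero (flow cannot be negative); a sign-preserving mode exists for noise
diagnostics. Voxels whose T1 fit has $R^2 \le 0.9$ (strict inequality for
inclusion) are excluded from the map statistics, mirroring standard
practice for low-SNR ASL.

## T1 mapping

`fit_ir_t1()` fits the three-parameter inversion-recovery model
$S(TI) = M_0(1 - 2\,\beta\,e^{-TI/T_1})$ voxel-wise by Levenberg–Marquardt
(T1 bounded to [50, 10000] ms, $\beta$ the inversion efficiency in [0, 1]).
EPI magnitude images lose the sign of the early-TI points, so the fit
restores polarity: candidate sign splits around the minimum-magnitude TI
are tried and the lowest-SSE signed fit kept. Initialization uses the
null-point heuristic ($T_1^{(0)} = TI_{\min|S|}/\ln 2$) and the longest-TI
frame for $M_0$. Degenerate voxels (constant series, undefined $R^2$) are
flagged non-converged and excluded, never silently filled.

`fit_vfa_t1()` handles the variable-flip-angle SPGR protocol (2°–20°):
linearization of $S/\sin\theta$ on $S/\tan\theta$ gives
$E_1 = e^{-TR/T_1}$ as the slope, refined by nonlinear least squares. When
the fitted slope leaves (0, 1) — e.g. $TR \gg T_1$, where the signal is
$\propto \sin\theta$ and carries no T1 information — the voxel is flagged
unidentifiable.

## Semi-quantitative DCE analysis

Enhancement is normalized to the precontrast baseline,
$\Delta SI(t) = (SI(t) - \overline{SI}_{base})/\overline{SI}_{base}$.
Bolus arrival per voxel is the first time $\Delta SI$ exceeds $k\,\delta$
($\delta$ = baseline SD of the enhancement; `k = 3` by default) sustained
for at least two consecutive dynamics; the persistence rule rejects
single-frame spikes. The exact threshold form used historically is not
standardized, so `k` is a configuration knob. The global bolus arrival is
the earliest voxel arrival, and AUC windows (60/90/150 s, or to each
voxel's $T_{max}$) are trapezoidal integrals from that arrival with linear
interpolation at the window edges. In noise-free data $\delta = 0$; the
detector then falls back to $\Delta SI > 0$ and says so.

## The digital phantom

`phantom_spec()` defines a 2D slice (default 64 × 48, 0.44 mm pixels)
holding a two-compartment tumor — a well-perfused rim around a low-flow
necrotic core — plus optional kidney-cortex disc and background tissue.
This geometry captures the perfusion heterogeneity (periphery vs core)
that makes tumor ASL hard, while staying simple enough that every derived
quantity has a closed form. Defaults, chosen once as representative of a
7 T xenograft protocol:

* flows: rim 90, core 10 mL/100 g/min (the span reported for xenograft
  tumors runs roughly 10–200, which the recovery tests cover);
* T1: rim 1600, core 1400, background 1500 ms;
* per-frame noise SD 2% of the signal level (`noise_sd = 0.02`,
  i.e. single-shot EPI SNR ≈ 50), 40 ASL repeats;
* DCE: gamma-variate enhancement, peak amplitude 1.5 (rim) / 0.4 (core),
  time-to-peak 25 / 60 s, shape 3, 100 dynamics at 3.1 s, bolus at
  dynamic 6.

Design notes:

* **Signed ASL frames.** The generator produces signed control/label
  signals so that the label-minus-control difference equals the kinetic
  model *exactly* plus zero-mean noise; each series receives per-frame
  noise of SD `noise_sd/sqrt(2)` so the difference noise has SD
  `noise_sd` of the signal level. The T1-mapping series, by contrast, is
  magnitude (as EPI magnitude images are), which is what exercises the
  polarity restoration.
* **Gamma-variate DCE curve.** Any unimodal curve would emulate a bolus;
  the gamma-variate is used because its partial integral has a closed form
  (`gamma_variate_auc()`, via the regularized incomplete gamma function),
  giving an independent oracle for the trapezoidal AUC.
* **Enhancement onset.** The onset sits half a dynamic (1.55 s) after the
  bolus by default. An onset placed exactly on the sampling grid has zero
  signal at its own sample — the "onset dynamic" would be ambiguous — so
  mid-interval onset makes the first enhanced sample well defined.
* **Noise model.** Additive Gaussian on the (signed) signals. At 40
  averages the magnitude SNR is high enough that the Rician correction
  would change nothing material; it is deliberately omitted.
* **Seeding.** One integer seed controls all draws; each series derives a
  deterministic sub-stream, and generation restores the caller's RNG
  state, so phantom calls never perturb surrounding code.

What the phantom does *not* emulate: EPI distortion and susceptibility
physics, motion, partial-volume mixtures at compartment borders, spatially
varying coil sensitivity, and biological heterogeneity beyond the
two-compartment split. Passing recovery tests therefore demonstrate the
*estimators*' correctness and noise behavior, not robustness to
acquisition artifacts — the QC module (Jaccard overlap gating at 0.6,
strict) is the guard for distortion in real data.

## The simulated treatment study

`simulate_treatment_study()` runs the full measurement chain per animal —
ASL + IR acquisition, T1 fit over the tumor, flow fit, quality filter, ROI
mean — for two cohorts whose group-mean flows default to 92.6 (control)
and 44.8 (treated) mL/100 g/min, the magnitude of a strong chronic
antiangiogenic response (treated ≈ 48% of control). Between-animal
variability of true flow uses a CV of 0.2, a typical inter-subject spread
for xenograft perfusion; in-vivo SDs reported for such studies are larger
(CV ≈ 0.36–0.46) because they fold in the biological heterogeneity noted
above, so the simulated study measures sensitivity of the *measurement
chain*, not a power analysis of the animal experiment. The cohort phantom
is homogeneous (no core) and small (16 × 12 grid, ~50 tumor voxels): the
inference target is the ROI mean, which does not require a large matrix,
and this keeps a 100-replicate study of 20 animals within a few minutes on
one CPU. These problem sizes are also the ones the package's validation
suite runs.

Group statistics follow the conventional design: two-tailed Student
t-tests for two-group endpoints, two-way ANOVA (group × time, with
interaction) plus cell-wise contrasts for pre/post designs, Pearson
correlation for cross-modality comparisons, significance at 0.05 with no
multiplicity correction (matching the practice the analysis emulates).

## Tumor growth and vessel metrics

Caliper volumes use the modified-ellipsoid formula
$V = \tfrac{1}{2}\,\text{length} \times \text{width}^2$ (length = longest
side). Growth inhibition is
$\%TGI = (V^{ctrl}_{X} - V^{trt}_{X})/(V^{ctrl}_{X} - V^{ctrl}_{0})
\times 100$; values above 100% mean regression below baseline.

Vessel metrics are computed from *binary* vessel masks (segmentation of
stained sections is upstream and out of scope): 8-connected components
(blob-like stains; a diagonal pair is one vessel) give the count, then
density = count/tissue area, size = vessel area/count, and area ratio =
vessel area/tissue area, so `area_ratio == density * size` is an exact
identity. No minimum-size filter is applied by default — commercial
segmentation pipelines apply undocumented filters, so the threshold is
exposed as an option rather than guessed.

## Numerical conventions and edge cases

* Strict inequalities at both quality gates ($R^2 > 0.9$, Jaccard
  $> 0.6$): a value exactly at the threshold fails.
* Two empty masks have Jaccard index 1 (vacuous agreement), with a
  warning, rather than NaN.
* $T_{max}$ ties break to the earliest dynamic; a constant curve reports
  the first dynamic.
* AUC windows extending past the acquisition integrate to the end and set
  a `truncated` flag; they are never silently extrapolated.
* Zero-baseline DCE voxels and all-NaN voxels carry `NA` sentinels and are
  excluded from every aggregate, with a count reported.
* Voxel indices in R interfaces are 1-based; all times/TIs are physical
  units (ms, s); masks are written as unsigned 8-bit NIfTI, maps as
  doubles.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(f_rim = 90, f_core = 10, noise_sd = 0.02,
                     n_repeats = 40, seed = 1)
asl <- generate_asl_series(spec)
ir  <- generate_ir_series(spec)
t1fit <- fit_ir_t1(ir, mask = asl$truth$tumor_mask)
dm  <- compute_delta_m(asl$control, asl$label)
pmap <- fit_perfusion(dm, t1fit, roi_mask = asl$truth$tumor_mask)
pmap$roi_mean   # ROI mean blood flow, mL/100 g/min
```

## Known limitations

* The partition coefficient is a global constant; in tumors it can vary
  regionally, which biases absolute flow by up to ~10% per 0.1 change in
  $\lambda$.
* Single-slice 2D analysis; no multi-slice labeling geometry.
* No transit-time estimation (adequate for thin-slice FAIR in mice, wrong
  for large inversion gaps).
* The DCE analysis is deliberately semi-quantitative; no arterial input
  function, Gd-concentration conversion, or Tofts-type modeling.
* The phantom's noise is Gaussian on signed signals; very-low-SNR
  magnitude data would need a Rician treatment the package does not
  implement.
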