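# tumorperf

Quantitative perfusion-MRI analysis of tumor treatment response, for
preclinical imaging scientists who measure how antiangiogenic therapy
changes tumor blood flow. The package covers the full chain used in
small-animal xenograft studies at 7 T:

* **FAIR-ASL blood-flow quantification.** The control/label difference
  signal per inversion time is fitted to the zero-transit-time solution of
  the general kinetic model,

  ```
  ΔM(TI) = 2 M0 α (f/λ) · (exp(−TI/T1app) − exp(−TI/T1a)) / (1/T1a − 1/T1app)
  ```

  with λ = 0.9 mL/g, T1a = 2210 ms, α = 1 by default, f the single free
  parameter per voxel (mL/100 g/min), and M0, T1app fixed from a
  voxel-wise three-parameter inversion-recovery T1 fit. Voxels with fit
  R² ≤ 0.9 are excluded (strict inequality).
* **T1 mapping** from inversion-recovery (with magnitude-polarity
  restoration) and variable-flip-angle SPGR series.
* **Semi-quantitative DCE-MRI**: baseline-normalized enhancement
  ΔSI(t) = (SI − SI₀)/SI₀, per-voxel bolus-arrival detection (k·δ
  threshold, sustained 2 dynamics), time of maximum enhancement, and
  trapezoidal AUC over 60/90/150 s windows after the global bolus arrival.
* **Distortion QC** by the Jaccard overlap index of ROIs drawn on two
  modalities, gated at J > 0.6.
* **ROI and group statistics**: caliper tumor volume (V = l·w²/2), %TGI,
  signed percent changes, Student t-tests, two-way ANOVA with cell-wise
  contrasts, Pearson correlation.
* **Microvessel metrics** from binary vessel masks: density, mean size,
  and area ratio from 8-connected components, with
  `area_ratio = density × size` exact.
* **A digital tumor phantom** (rim/core compartments with known flow, T1,
  and gamma-variate enhancement truth) so that every stage is testable
  end to end without acquired data.

## Worked example

Simulate a heterogeneous tumor (rim 90, necrotic core 10 mL/100 g/min) at
the standard protocol — TIs 100–4000 ms, 40 measurements, 2% per-frame
noise — then quantify it:

```r
library(tumorperf)

spec  <- phantom_spec(f_rim = 90, f_core = 10, noise_sd = 0.02,
                      n_repeats = 40, seed = 1)
asl   <- generate_asl_series(spec)
ir    <- generate_ir_series(spec)
t1fit <- fit_ir_t1(ir, mask = asl$truth$tumor_mask)
dm    <- compute_delta_m(asl$control, asl$label)
pmap  <- fit_perfusion(dm, t1fit, roi_mask = asl$truth$tumor_mask)

round(c(roi_mean = pmap$roi_mean, roi_sd = pmap$roi_sd), 1)
#> roi_mean   roi_sd
#>     75.4     31.9
mean(asl$truth$f_map[asl$truth$tumor_mask])   # ground truth ROI mean
#> [1] 75.30612
```

The ROI mean of 75.4 mL/100 g/min recovers the phantom's true mean (75.3)
to well within the noise floor; the large ROI SD reflects the genuine
rim/core flow contrast, not fit error. Group-level effect sizes are
computed the same way as in a treatment study:

```r
percent_change(92.6, 44.8)   # chronic treated vs control group means
#> [1] -51.6
```

A thin command-line front end is included at `inst/cli/tumorperf.R`
(`simulate`, `run`, `fit-t1`, `fit-asl`, `dce`, `qc-jaccard`, `vessels`),
and `run_pipeline()` drives the same stages from a YAML configuration with
full provenance (resolved config, logs, NIfTI maps, CSV summaries) under
one run directory.

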