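Package: tumorperf
Title: Quantitative Perfusion MRI Analysis of Tumor Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative perfusion MRI of tumor
    xenografts: FAIR arterial spin labeling blood-flow quantification with a
    zero-transit-time kinetic model, voxel-wise inversion-recovery and
    variable-flip-angle T1 mapping, semi-quantitative dynamic
    contrast-enhanced (DCE) MRI enhancement analysis (bolus arrival, time to
    peak, area under the enhancement curve), Jaccard-index distortion quality
    control, ROI and treatment-group statistics, and microvessel metrics from
    binary vessel masks. Includes a digital tumor phantom generator with
    known ground truth so every stage can be validated end to end without
    acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
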