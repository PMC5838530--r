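Package: rtnf
Title: Real-Time fMRI Neurofeedback Training Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for closed-loop real-time fMRI
    neurofeedback training studies of the kind used in Huntington's disease
    proof-of-concept trials. Implements the feedback-signal computation
    (hemodynamic-response-weighted baseline estimation, percent signal change,
    operant shaping of the thermometer scale), functional-localizer GLM fitting
    and t-map based target-ROI selection, offline analyses (motion scrubbing,
    block contrasts, linear mixed-effects visit trends, psychophysiological
    interaction connectivity, voxelwise behaviour regression), clinical
    composite scoring (CAP score, direction-harmonized standardized measure
    panels, quantitative-motor tapping metrics), and a synthetic BOLD and
    cohort generator with recorded ground truth so that every stage is
    testable end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
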