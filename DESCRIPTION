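Package: glucodot
Title: Glucose Variability and Task-Free DOT Connectivity in Preterm Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking continuous glucose monitoring (CGM)
    variability to changes in task-free functional connectivity (tfFC)
    measured with diffuse optical tomography (DOT) in preterm neonates.
    Provides CGM event classification and glycemic metrics, quality-driven
    selection of 5-minute DOT windows (channel pruning, spectral screening,
    sensitivity coverage), optical-density preprocessing with wavelet motion
    correction and band-pass filtering, Tikhonov image reconstruction with
    hemoglobin spectral unmixing, ROI-based Fisher-Z connectivity statistics
    with false-discovery-rate control, and cohort-level association between
    connectivity change and glucose metrics. A synthetic cohort generator
    with known ground truth (analytic semi-infinite photon-diffusion forward
    model, planted ROI correlations, planted glucose-connectivity relations)
    supports end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, signal, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), MASS, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
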