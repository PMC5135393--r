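Package: tectalamina
Title: Laminar Segregation Analysis of Evoked Tectal Field Potentials
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of laminar evoked field-potential recordings from the
    developing optic tectum: peak field-potential quantification along the
    distal-proximal neuropil axis, per-tectum normalization and spatial
    profiles, discrete current-source-density (CSD) estimation with a
    configurable spatial differentiation grid, sink localization, spatial
    overlap indices between afferent inputs, fluorescence line-profile
    quantification of labeled axons, and normality-routed two-group
    statistics. Includes a self-consistent forward model that simulates
    recordings with known ground truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Electrophysiology, Visualization, Software
RoxygenNote: 7.3.3
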