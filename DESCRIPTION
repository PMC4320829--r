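Package: meadev
Title: Quantitative Analysis of Developing Spontaneous Activity on
    Multielectrode Arrays
Version: 0.1.0
Authors@R:
    person("MEA", "Tools", email = "meadev@example.org", role = c("aut", "cre"))
Description: Tools for characterising spontaneous spiking activity recorded
    from neuronal cultures on multielectrode arrays (MEAs) across development.
    Provides max-interval burst detection, network-spike detection from binned
    population activity, pairwise spike time tiling coefficients (STTC),
    theta-burst detection from smoothed log-ISI densities, and assembly of an
    11-feature summary vector per recording.  Downstream statistics include
    per-age Mann-Whitney comparisons with false-discovery-rate correction,
    principal component projections, and classification of recordings
    (random forest with Gini importance, radial-kernel SVM) into hippocampal
    versus cortical network types.  A synthetic-recording generator with
    region/age presets supports calibration and power analysis, and HDF5
    import/export is compatible with the layout used for archived
    multielectrode-array culture recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    rhdf5,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
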