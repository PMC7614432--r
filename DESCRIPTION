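Package: lagcvr
Title: Haemodynamic Lag and Cerebrovascular Reactivity Mapping for Stroke fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise haemodynamic lag mapping of BOLD fMRI by discrete
    cross-correlation against a grey-matter reference signal with parabolic
    peak interpolation, and breath-hold cerebrovascular reactivity (CVR)
    mapping with voxelwise end-tidal CO2 delay optimisation. Includes
    frame-level motion quality control (framewise displacement, scrubbing),
    nuisance regression and cosine high-pass filtering, lesion-anchored
    region-of-interest construction (lesion, perilesional shell, remote
    tissue and their hemispheric homologues), the associated subject- and
    group-level statistics (Spearman lag-CVR correlation with Wilcoxon
    signed-rank group inference, cross-condition spatial correlation,
    voxelwise two-factor OLS ANOVA with Benjamini-Hochberg FDR control), and
    a synthetic 4D BOLD phantom generator with known ground truth for
    validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
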