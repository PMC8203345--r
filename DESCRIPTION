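Package: gfcmap
Title: Voxel-Wise Global-Brain Functional Connectivity Analysis of
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-subject voxel-wise global-brain functional
    connectivity (GFC, also called global brain connectivity) maps from
    preprocessed resting-state fMRI volumes over a gray-matter mask, with
    Fisher r-to-z transformation; performs covariate-adjusted voxel-wise
    two-sample group inference with permutation-based (max-T,
    Freedman-Lane) or Bonferroni family-wise error control and
    26-connected cluster extraction with peak MNI coordinates; screens
    Pearson correlations between cluster-mean GFC and clinical variables
    with Bonferroni control; and classifies patients versus controls from
    single-region cluster means with a leave-one-out cross-validated
    RBF-kernel support vector machine. Includes a fully specified
    synthetic-cohort generator (4D BOLD volumes, gray-matter probability
    map, rigid-body motion traces, clinical table, ground truth) so the
    whole pipeline is testable without access to patient data, plus
    frame-wise displacement motion quality control and an end-to-end
    pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    SummarizedExperiment,
    S4Vectors,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
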