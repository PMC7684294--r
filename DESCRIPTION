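Package: painsig
Title: Multivariate Brain-Signature Expression and Somatovisceral Pain Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the expression of multivariate brain
    signatures (e.g. the Neurologic Pain Signature) in subject-level fMRI
    contrast maps, for classifying pain versus no-pain and visceral versus
    somatic pain from resting-state-network similarity features, and for
    voxel-wise group GLM analysis with FDR thresholding and minimum-statistic
    conjunction. Includes signature-expression scoring (dot product and cosine
    similarity), Hedges-Olkin effect-size confidence intervals, forced-choice
    and single-interval classification statistics, binormal ROC models,
    cross-validated network-based logistic classification, robust (IRLS,
    bisquare) brain-behaviour regression with weighted correlations, and a
    synthetic multi-study cohort generator so that every stage of the pipeline
    can be exercised and validated without access to real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    MASS,
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
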