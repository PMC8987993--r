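Package: brainpad
Title: Brain-Age Modeling and Normative Deviance Profiling for Regional MRI Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Modality-specific brain-age prediction from regional gray- and
    white-matter MRI feature tables using a cascade feed-forward network,
    age-bias-corrected predicted-age-difference (PAD) scores,
    Gaussian-process normative models that convert regional features into
    standardized deviance Z-scores, robust (MM-estimate) feature
    contribution profiles, and the accompanying group-level statistics
    (ANCOVA with covariates, Benjamini-Hochberg post-hoc correction,
    partial correlations, Fisher r-to-z comparison of correlations).
    Includes a synthetic cohort generator with known ground truth so the
    whole pipeline can be exercised and validated end-to-end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, MASS, S4Vectors, jsonlite, yaml,
    data.table, withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cascade.R'
    'featureTable.R'
    'brainAge.R'
    'brainpad-package.R'
    'cohort-io.R'
    'utils.R'
    'contribution.R'
    'descriptors.R'
    'groupStats.R'
    'normative.R'
    'pad.R'
    'trajectories.R'
    'simulate.R'
    'pipeline.R'
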