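Package: terroirPLS
Title: Confounder-Aware Constrained PLS-DA for Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Latent-variable chemometrics for untargeted LC-MS/GC-MS feature
    tables collected under confounded designs, where a dominant nuisance
    factor (e.g. harvest vintage) masks the class structure of interest
    (e.g. geographic origin). Implements orthogonal constrained PLS2-DA
    (oCPLS2-DA), in which latent scores are forced orthogonal to a nuisance
    block inside the NIPALS weight-maximisation step, together with
    post-transformation of fitted PLS models to N-1 predictive components,
    OPLS-DA, N-fold full cross-validation with Q2 and permutation testing,
    split-plot ANOVA screening, median fold change and internal-standard
    normalisation, correlation-loading marker extraction, and a synthetic
    data generator emulating a multi-vineyard, multi-vintage study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils.R'
    'AllClasses.R'
    'io.R'
    'preprocess.R'
    'nipals.R'
    'latentCore.R'
    'ocpls.R'
    'opls.R'
    'posttransform.R'
    'validation.R'
    'splitplotAnova.R'
    'markers.R'
    'synthetic.R'
    'pipeline.R'
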