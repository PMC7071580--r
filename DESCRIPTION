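Package: titrassess
Title: Assessment of 16S rRNA Marker-Gene Count Tables Using Two-Sample
    Titration Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Benchmarking framework for count tables produced by 16S rRNA
    marker-gene survey bioinformatic pipelines, based on a two-sample
    titration mixture design. Unmixed samples mixed along a log2 dilution
    series yield expected feature proportions and expected log fold-changes
    against which any pipeline's count table can be scored. The package
    provides qualitative assessment of feature presence/absence (binomial
    and Monte Carlo Bayesian sampling tests for unmixed-specific and
    titration-specific features, with Benjamini-Hochberg correction),
    estimation of the realized mixture proportion from the sequence data,
    quantitative assessment of relative and differential abundance
    (feature-level bias and variance metrics), cross-pipeline comparison
    via mixed-effects models with Tukey HSD, and a synthetic titration
    data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    lme4,
    jsonlite,
    biomformat
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
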