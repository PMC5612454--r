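Package: ssrsa
Title: Spatiotemporal Searchlight Representational Similarity Analysis for
    Source-Space Neural Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating time-varying model representational
    dissimilarity matrices (RDMs), built from frame-level phonetic-class
    log-likelihood streams, to data RDMs computed from source-space
    electrophysiological response patterns with a spatiotemporal searchlight.
    Provides RDM construction and comparison primitives, dynamic (windowed)
    RDM streams for phone models and brain data, simultaneous multi-model
    GLM fitting of phone model RDMs to data RDMs, aggregation of phone
    coefficients into articulatory-feature fits, permutation-based null
    distributions with per-feature quantile thresholds, second-order
    model-space diagnostics (Spearman similarity, Davies-Bouldin index,
    eta-squared, non-metric MDS), and a synthetic-data generator that
    implants known representational geometry for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
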