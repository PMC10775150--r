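Package: stericsel
Title: Steric Pocket Descriptors and Nonlinear Selectivity Modeling for
    Conformer Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes probe-based axial-pocket cavity descriptors
    (cavity volume, entry surface area, proximal/distal partitions),
    shadow-cone shielding descriptors (G%, G% surface), Sterimol L/B1/B5
    and sphericity from Boltzmann-weighted conformer ensembles of
    paddlewheel dirhodium catalysts and related structures; converts
    diastereomeric ratios to activation free-energy differences; fits
    sparse nonlinear selectivity models by operator expansion of base
    descriptors with sure-independence screening and exhaustive
    small-subset least squares (SISSO-style); and deconvolutes
    catalyst-substrate chemical space with PCA, K-means clustering and
    regression trees. Includes deterministic synthetic generators for
    toy catalyst ensembles and planted-signal reaction benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'vdw.R'
    'geometry-io.R'
    'reaction.R'
    'sisso-features.R'
    'sisso-fit.R'
    'metrics.R'
    'chemspace.R'
    'fixtures.R'
    'tree.R'
    'splits.R'
    'pipeline.R'
    'pocket.R'
    'shadow.R'
    'stericsel-package.R'
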