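Package: nucassoc
Title: Chromatin Segment Association Analysis with a Random Spatial
    Distribution Null Model
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores fluorescence in situ hybridization (FISH) signal
    configurations in flow-sorted interphase nuclei (association of
    euchromatin segments in cis and trans, chromatin fiber elongation,
    sister-chromatid cohesion, adjacent-segment separation, out-looping
    from chromosome territories), compares observed association
    frequencies against a Monte-Carlo Random Spatial Distribution (RSD)
    null model of disc-shaped signal areas placed at random in a virtual
    nucleus using the two-sided Fisher's exact test, and relates
    association to gene co-expression via Spearman rank correlation on
    log2 mean-normalized expression matrices. Includes a fully seeded
    synthetic-data generator for scored-nuclei tables and block-correlated
    expression matrices so that every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rlang,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, FISH, Spatial, StatisticalMethod, GeneExpression
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'coexpression.R'
    'exact-tests.R'
    'scoring.R'
    'rsd.R'
    'synthetic.R'
    'io.R'
    'nucassoc-package.R'
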