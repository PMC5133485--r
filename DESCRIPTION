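Package: murat
Title: Multivariate Rare-Variant Association Testing for Correlated Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based rare-variant association testing for multiple
    correlated continuous phenotypes. Implements a multivariate score test
    (MURAT) that couples per-variant random effects across phenotypes through
    a common effect correlation, together with the univariate sequence kernel
    association test (SKAT) for comparison, an analytic quadratic-form
    p-value engine (Imhof characteristic-function inversion with a
    moment-matching fallback), genome-scan orchestration over single
    variants, genes and fixed-width windows with Bonferroni and
    minimum-p adjustments, and a synthetic-data generator for size and
    power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
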