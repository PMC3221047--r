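Package: patternComp
Title: Pattern-Component Decomposition of Multivoxel Activity Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes trial-by-voxel activation estimates into random
    pattern components using a linear mixed model. The variance-covariance
    matrix of the components is constrained through a basis-matrix
    factorisation G = A A' and estimated by expectation-maximisation,
    yielding corrected between-condition correlations that are invariant to
    measurement noise, common (nonspecific) activation and voxel selection.
    Hidden patterns are recovered by best linear unbiased prediction, and
    their spatial smoothness is summarised by fitting squared-exponential
    autocorrelation kernels. Includes synthetic-data generators for the
    supported designs and scenario-grid drivers for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'builders.R'
    'utils.R'
    'estimation.R'
    'spatial.R'
    'similarity.R'
    'simulate.R'
    'scenarios.R'
    'io.R'
    'patternComp-package.R'
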