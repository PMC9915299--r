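Package: adhevol
Title: Volumetric Assessment of Orthodontic Adhesive Clean-Up from 3D
    Surface Scans
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the outcome of orthodontic clean-up procedures from
    triplets of aligned 3D surface scans of a tooth (baseline, post-debond,
    post-clean-up). Provides STL mesh input/output, region-restricted rigid
    best-fit (ICP) registration, signed surface deviation mapping, clipping
    to a 5 mm region of interest, watertight closed-shell construction by
    extrusion, and clearance-aware Boolean difference volumetry yielding
    adhesive volume, residual adhesive volume, relative residual adhesive
    fraction and enamel volume loss. A statistical layer applies power
    transform normalization with Shapiro-Wilk gating, one-way ANOVA and
    Tukey HSD across treatment groups, plus a-priori sample size
    computation. A synthetic structured-light scan simulator with known
    ground-truth volumes supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'geometry-io.R'
    'transforms.R'
    'registration.R'
    'roi.R'
    'volumetry.R'
    'stats.R'
    'synthetic.R'
    'pipeline.R'
    'adhevol-package.R'
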