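Package: mdmrvol
Title: Multivariate Distance Matrix Regression for Brain Network Volumetrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distance-based multivariate analysis of regional brain volumes
    within intrinsic networks (fronto-parietal and default-mode). Implements
    multivariate distance matrix regression (MDMR) with Gower centering and
    Freedman-Lane permutation inference, jack-knife permutation effect sizes
    that attribute multivariate group differences to individual regions,
    distance-based redundancy analysis (dbRDA) ordination with exact group
    centroid geometry, univariate post-hoc regressions, and a synthetic
    cohort generator with planted group and sex effects so the full pipeline
    can be exercised and calibrated without access to restricted MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
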