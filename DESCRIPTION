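Package: pvsmorph
Title: Computational Quantification of Perivascular Spaces on Structural MRI
Version: 0.1.0
Authors@R: person("pvsmorph", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for computational assessment of perivascular spaces
    (PVS) in the centrum semiovale on T2-weighted structural MRI: anisotropic
    reslicing to 1 mm isotropic voxels, multiscale three-dimensional Frangi
    vesselness filtering, connected-component extraction of tubular candidates
    under explicit morphological constraints, per-PVS ellipsoid morphometry,
    and per-subject aggregate measures including an emulated ordinal visual
    rating. Includes a synthetic phantom generator with ground truth for
    validation, a cohort simulator with configurable effect structure, and the
    cohort statistical battery (polyserial and Pearson correlation, Welch t,
    chi-squared, linear, logistic and beta regression with logit link,
    AIC/BIC model comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
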