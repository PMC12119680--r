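Package: ecaccess
Title: Travel Time to Emergency Care and Severity of Paediatric Anaemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how modelled travel time to hospital
    emergency care relates to the severity of paediatric anaemia at
    admission. Builds friction surfaces from road and land-cover rasters,
    computes least-cost-path travel times to a referral hospital, adjusts
    haemoglobin for altitude and classifies anaemia severity, applies a
    reproducible inclusion/exclusion cascade, produces distance-decay
    descriptive statistics (admission rates per 1,000 children, Wilson
    intervals, Kruskal-Wallis and Fisher tests, crude odds ratios), and
    fits a Bayesian Bernoulli-logit model with a Matern-covariance
    Gaussian-process spatial random effect over enumeration-area
    centroids by Laplace approximation. A synthetic-region generator
    with known ground truth supports end-to-end testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    igraph,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
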