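Package: mcatsim
Title: Multidimensional Computerized Adaptive Testing Simulation and
    Item Usage Analysis
Version: 0.1.0
Authors@R:
    person("mcatsim", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulation engine for multidimensional computerized adaptive
    tests (MCAT) built on the between-item multidimensional graded response
    model. Provides maximum a posteriori (MAP) latent-trait estimation with
    a correlated multivariate-normal prior, D-optimal (posterior-information
    determinant) item selection, per-dimension standard-error termination,
    grid-based simulation studies, and item-usage analytics (usage rates,
    overuse, active bank size, overlap, RMSE/bias), together with a
    synthetic item-bank generator emulating a four-domain health-related
    quality-of-life bank.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
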