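Package: moransync
Title: Spatial Synchrony and Transient Periodicity in Multi-Site Occupancy Time-Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spatial population synchrony in multi-site
    occupancy survey data. Builds occupancy-rate and log growth-rate series
    from site-year survey tables, fits growth-rate regressions on weather,
    food and predator covariates with site fixed effects and collinearity
    diagnostics, quantifies between-site synchrony with a weighted
    penalized-spline correlogram on Fisher-z-transformed pairwise Pearson
    correlations (bootstrap and Mantel-type permutation null models), and
    detects transient periodicity with a pooled bias-corrected Morlet wavelet
    spectrum and a Gaussian cell-wise significance rule. Includes a
    Moran-effect simulator (distance-decaying correlated environmental
    forcing driving Gompertz density-dependent local dynamics, observed
    through binomial occupancy counts) so every stage can be tested against
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), geosphere, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
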