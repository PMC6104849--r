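Package: cesviews
Title: Viewshed-Intensity Mapping of Cultural Ecosystem Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and modelling the visual landscape qualities
    that contribute to cultural ecosystem services from georeferenced photo
    locations. Builds a digital surface model from a LiDAR-style point cloud
    by max-Z binning, computes per-photo raster viewsheds by line of sight,
    accumulates them into a viewshed-intensity surface, validates photo
    content labels against viewshed-visible land cover with percent agreement
    and Cohen's kappa, and models intensity counts with a negative-binomial
    regression whose dispersion is selected by AIC. Includes a synthetic
    landscape generator with known ground truth so the full pipeline can be
    exercised end to end, plus spatial diagnostics (variance inflation
    factors, Moran's I on residuals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    mgcv,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
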