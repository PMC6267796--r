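Package: sitstand
Title: Forward Simulation of Sit-to-Stand Hip Joint Contact Forces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-dimensional sagittal-plane forward simulation of sit-to-stand
    movements. Generates a grid of seat-off postures, synthesizes cosine-curve
    joint trajectories, computes joint moments and the hip intersegmental force
    by Newton-Euler inverse dynamics, resolves the eight-muscle redundancy
    problem per frame by static optimization (convex quadratic programming),
    and computes the hip joint contact force from the intersegmental force and
    the hip-spanning muscle forces along their lines of action. Includes a
    four-parameter sensitivity analysis (objective function, PCSA, moment arm,
    force-length ability) and study-level summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
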