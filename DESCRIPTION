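Package: stereofid
Title: Fiducial Localization and Registration Accuracy for Frame-Based
    Stereotaxy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Geometry, solvers, and Monte Carlo accuracy simulation for
    fiducial-based registration of computed tomography images to a
    stereotactic frame. Models V-shaped Sturm-Pastyr localizers and
    N-localizers attached to a Zamorano-Dujovny-style frame, computes
    frame coordinates of rod intersections from measured fiducial
    centers (both the classic one-point solve and a three-point solve
    that exploits all three inter-fiducial distances), fits the
    overdetermined image-to-frame transformation by least squares, and
    quantifies target registration error under bounded fiducial-center
    noise with a seeded, vectorized Monte Carlo engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
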