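Package: capflow
Title: Pressure-Balance Modelling of Capillary Rise in Multi-Bore
    Microfluidic Strips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of vertical capillary rise in multi-bore
    ('dip stick') microfluidic strips. Implements the quasi-steady pressure
    balance between Laplace, viscous-friction and hydrostatic pressures in
    elliptical microcapillaries, a trajectory simulator with dose-dependent
    viscosity ramps emulating thrombin-stimulated blood, a synthetic
    time-lapse frame renderer with sub-pixel meniscus tracking, and
    box-constrained recovery of dynamic viscosity and the combined surface
    property cos(theta)*gamma from instantaneous-velocity data. The central
    interface is capillary_fit(), which returns a classed model object with
    the usual print, summary, coef, predict, plot, residuals and simulate
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
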