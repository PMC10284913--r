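Package: fractumor
Title: Fractional-Order Tumor Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits classical and Caputo fractional-order tumor growth laws
    (exponential, logistic, Gompertz, generalized and particularized
    Bertalanffy-Putter) to tumor-volume time series. Provides a fractional
    Adams-Bashforth-Moulton initial-value-problem solver, Mittag-Leffler
    function evaluation, Riemann-Liouville integral and Caputo derivative
    quadratures, a two-stage mean-squared-error fitting procedure
    (Nelder-Mead over kinetic parameters at integer order, then a
    one-dimensional search over the fractional order), existence/uniqueness
    and Mittag-Leffler stability diagnostics, and a seeded synthetic
    experiment generator emulating a treated/untreated mouse xenograft
    protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
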