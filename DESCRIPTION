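Package: exgaussrt
Title: Ex-Gaussian Decomposition of Masked-Priming Response Times
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <maintainer@example.com>
Description: Simulation, preprocessing and ex-Gaussian (mu, sigma, tau)
    decomposition of response times from masked-priming recognition
    experiments. Fits are obtained by maximum-ascent likelihood search from
    moment-based starting values, goodness of fit is calibrated by
    parametric-bootstrap Kolmogorov-Smirnov p-values, and parameter
    uncertainties are derived from the iso-likelihood surface half a
    log-likelihood point below the maximum.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
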