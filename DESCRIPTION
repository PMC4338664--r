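Package: evsn
Title: Unsupervised Spatiotemporal Feature Learning for Event-Based Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns dynamic visual features from the address-event output of a
    change-based vision sensor (silicon retina). Events are pooled into cells
    and filtered with a causal exponential kernel into an analog vector; a
    bank of echo-state networks predicts the vector one tick ahead, trained
    online with recursive least squares; a spiking winner-take-all circuit
    with an adaptive sigmoid encoder and predictability-minimization
    inhibition grants, each millisecond, training to the single best
    non-redundant predictor, so the bank self-organises into distinct
    spatiotemporal feature detectors. Includes a sensor emulator (moving
    oriented bars, jittered digit bitmaps, Poisson background noise) so the
    whole pipeline runs without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
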