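Package: tpnmrds
Title: Mark-Recapture Distance Sampling with a Two-Piece Normal Detection Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates wildlife abundance from dual-observer aerial line-transect
    surveys using mark-recapture distance sampling (MRDS) under point independence.
    The distance model is a two-piece normal multiple-covariate detection function
    whose apex lies off the transect line, as arises with flat-windowed survey
    aircraft; the mark-recapture model is a conditional multinomial logistic model
    for pilot/backseat-observer capture histories. Provides stratified
    Horvitz-Thompson abundance estimation with encounter-rate and model variance
    components, log-normal confidence intervals, AIC forward model selection with
    chi-square, Kolmogorov-Smirnov and Q-Q goodness of fit, harvest-rate estimation
    for biennial and annual hunt schemes, and a synthetic dual-observer survey
    generator for validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
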