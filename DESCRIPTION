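Package: ecapipg
Title: Analysis of eCAP Growth Functions, Neural Synchrony, and the
    Interphase-Gap Effect in Cochlear Implant Users
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing electrically evoked compound action
    potentials (eCAPs) recorded through cochlear implants. Computes
    trial-to-trial phase locking values (PLV) from repeated eCAP sweeps via
    a Hanning-tapered short-time Fourier transform, extracts amplitude
    growth function (input/output) features -- eCAP threshold, maximum
    amplitude, dynamic range, overall linear slope, and the sliding-window
    maximum slope -- on linear and logarithmic stimulus/amplitude scales,
    fits sigmoidal and exponential growth models by nonlinear least
    squares, and quantifies the interphase-gap (IPG) effect, including the
    stimulation level offset evaluated at the 25/50/75% quantiles of the
    overlapping amplitude range via sigmoid inversion. A seeded synthetic
    data module simulates eCAP sweep sets and paired-IPG growth functions
    (including the quadratic forward model V = r*n*(s*g*I)^2) so that
    every stage of the pipeline can be exercised and validated without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    jsonlite,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
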