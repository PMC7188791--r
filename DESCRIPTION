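Package: denitvial
Title: Sealed-Vial Denitrification Kinetics: Simulation, Sampling Emulation
    and Electron-Flow Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic model of aerobic respiration and four-step
    denitrification (NO3- -> NO2- -> NO -> N2O -> N2) by a halophilic
    archaeon growing in sealed, stirred serum vials, including gas-liquid
    partitioning by Henry's law with Setschenow salting-out, a hypoxia/NO
    transcriptional regulation model with a micro-oxic gate on enzyme
    synthesis, and an emulator of robotized headspace sampling with helium
    back-fill.  An inference pipeline converts the resulting gas and
    nitrite time series into dilution-corrected production rates, per-
    reductase nitrogen rates, electron flows, apparent specific growth
    rates from log-linear regression, generation counts, and N-oxide
    accumulation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
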