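Package: optocochlea
Title: Forward Modelling of Optoacoustic Cochlear Stimulation by Pulsed Laser Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing laser-evoked optoacoustic
    pressure waves of the kind used for intra-cochlear optical stimulation.
    The package models laser pulse temporal profiles and their time
    derivative, thermal and stress confinement criteria, Beer-Lambert
    absorption calibration (including an India-ink dilution series), a
    retarded-time volume-integral acoustic forward model from the
    energy-deposition profile at an optical fiber tip to a hydrophone-like
    field point, a band-limited measurement chain, and a compound action
    potential (CAP) surrogate stage. Seeded synthetic-data generators and
    scripted parameter sweeps (constant pulse energy, constant peak power,
    absorption coefficient) reproduce the structure of water-tank
    optoacoustic experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
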