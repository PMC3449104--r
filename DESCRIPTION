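Package: pnporin
Title: One-Dimensional Poisson-Nernst-Planck Modelling of Selectivity and
    Conductance in Wide Ion Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the transport properties of wide, multi-ionic
    protein channels such as the bacterial porin OmpF. Implements a steady-state
    one-dimensional Poisson-Nernst-Planck electrodiffusion solver driven by an
    axial effective fixed-charge profile (with an optional electroneutral
    Teorell-Meyer-Sievers closure with Donnan interfaces), Henderson
    liquid-junction potentials and salt-bridge corrections for reversal-potential
    measurements, electrolyte activity and conductivity handling with effective
    salt-dependent diffusion coefficients, and pH/divalent-cation titration of
    the channel fixed charge. A synthetic-data layer generates charge profiles,
    salt property tables, and noisy pseudo-experimental reversal-potential and
    conductance datasets for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
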