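Package: casrcoop
Title: Cooperativity Analysis of Calcium-Sensing Receptor Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify functional cooperativity of the calcium-sensing
    receptor (CaSR) from single-cell calcium imaging, population dose-response
    assays and structural ensembles. Quantifies extracellular-calcium-evoked
    intracellular calcium oscillations by three parameters (starting point,
    frequency, ending point), fits monophasic and biphasic Hill models to
    calcium, inositol-1-phosphate and phospho-ERK readouts, measures the
    left-shift produced by the allosteric modulator L-phenylalanine, and
    computes residue-residue dynamic cross-correlation maps and
    principal-component projections from coordinate ensembles. A synthetic-data
    generator emulating stepwise agonist protocols, cell-to-cell threshold
    heterogeneity and covariance-structured ensembles makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    MASS,
    bio3d,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
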