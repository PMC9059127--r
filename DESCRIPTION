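Package: hdoshell
Title: Quantitative Difference-Spectra Analysis of Solute-Affected Water from HDO Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isolating and quantifying solute-affected water from
    titration series of HDO OD-stretch infrared spectra by the quantitative
    difference-spectra method. For a single solute the package extracts the
    affected-water spectrum and the affected number N (moles of water per mole
    of solute); for two-solute systems it computes "experimental" and
    "synthetic" (no-interaction) affected spectra, isolates the double-affected
    water spectrum, and classifies the interaction regime (cross-linking versus
    shared hydration spheres). Band descriptors (gravity center, band maximum)
    and O...O hydrogen-bond distance distributions obtained through an
    empirical wavenumber-distance correlation characterize hydrogen-bond
    energetics. A forward generator of synthetic titration series with known
    ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
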