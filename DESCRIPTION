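Package: depclog
Title: Dielectrophoretic Anti-Clogging Analysis for Microfluidic Blood Plasma Separators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical design tools for dielectrophoresis (DEP) based
    anti-clogging in microfluidic blood plasma separation devices. Computes
    complex permittivities, Clausius-Mossotti factor spectra (homogeneous and
    core-shell cell models), DLVO adhesion forces (van der Waals plus
    electrostatic double layer) against the negative-DEP repulsive force over
    an interdigitated electrode array, separation performance statistics
    (cell loss, purity efficiency, plasma yield), and a stochastic
    Lagrangian simulator of cell capture, aggregation and clogging in a
    bifurcating 50-branch channel network, driven by a synthetic blood-cell
    population generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
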