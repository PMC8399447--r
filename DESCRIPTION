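Package: boltzbands
Title: Boltzmann-Weighted Conformer Ensembles and Raman Band Tracking for
    Acidic Peptide Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of conformer ensembles of short glutamate-rich peptide
    fragments (the beta-tubulin E-hook EGEDEA and the fragments that build it).
    Computes Maxwell-Boltzmann conformer populations from relative energies,
    simulates Raman spectra by Lorentzian broadening of scaled harmonic
    frequencies weighted by Raman activities, forms Boltzmann-summed ensemble
    spectra, assigns and tracks the amide I and C-terminal carboxylate
    nu(C=O) bands across a fragment series, aggregates intramolecular
    hydrogen-bond charge transfer from natural-population atomic densities,
    and summarises backbone phi/psi geometry with Boltzmann-weighted circular
    means.  Ships the tabulated per-conformer reference data for the eleven
    fragments as plain-text fixtures and a synthetic-ensemble generator so
    the full pipeline is testable without any electronic-structure software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
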