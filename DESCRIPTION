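Package: jaggpath
Title: Thermodynamic and Kinetic Analysis of Competing J-Aggregation Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dissecting pathway complexity in supramolecular dye
    polymerization. Implements the mass balance of a cooperative (K2-K)
    nucleation-elongation pathway competing with an off-pathway dimerization,
    fits the three equilibrium constants to concentration-dependent UV/vis
    and circular dichroism observables by variable-projection nonlinear
    least squares, converts constants to standard Gibbs energies and
    assembles the energy landscape, and estimates initial transformation
    rates d(g)/dt from anisotropy-factor time courses. A calibrated
    synthetic-data generator reproduces the spectroscopic signatures of a
    zinc chlorin model system (monomer, kinetically trapped nanoparticle
    dimers, equilibrated helical J-aggregate fibers) for round-trip
    validation of the whole analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
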