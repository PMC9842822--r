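Package: helixhb
Title: Backbone Hydrogen-Bond Energetics of Alpha- and 3-10-Helices by
    Negative Fragmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ideal capped poly-alanine alpha- and 3-10-helix models
    from internal coordinates, enumerates their backbone hydrogen bonds, and
    quantifies individual hydrogen-bond energies with the Negative
    Fragmentation Approach (NFA) inclusion-exclusion scheme, applied to
    total energies and to volumetric electron-density grids. Includes the
    classical point-charge/Lennard-Jones hydrogen-bond energy, a
    dipole-polarized backbone-charge correction with neighbour
    peptide-group dipole-dipole couplings, and a damped least-squares
    fitter for the four polarization coefficients, together with a text
    adapter for an external quantum-chemistry engine (input writer, energy
    and cube-file parsers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
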