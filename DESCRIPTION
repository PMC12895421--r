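Package: longrangefit
Title: Symmetry-Adapted Multipole Expansions of Long-Range Intermolecular
    Interactions and Their Fitting to Scattered Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic generation of the symmetry-adapted spherical-tensor
    multipole expansion of the long-range interaction energy (electrostatic,
    induction and dispersion, up to 15th order in 1/R) between two rigid
    molecules of arbitrary point-group symmetry and charge, and staged
    nonlinear least-squares determination of the expansion coefficients from
    scattered interaction-energy data.  Includes exact point-charge Coulomb
    oracles, term tables by interaction type and order, a LeRoy-type
    anisotropy filter, outlier diagnostics, synthetic-data generation for
    validation, coefficient serialization and export of a standalone Fortran
    evaluator of the fitted potential.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
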