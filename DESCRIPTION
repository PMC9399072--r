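Package: phasefit
Title: Dihedral Phase-Shift Prediction and Bonded-Parameter Fitting for
    CHARMM-Style Force Fields
Version: 0.1.0
Authors@R:
    person("Maintainer", "phasefit", email = "phasefit@example.org",
           role = c("aut", "cre"))
Description: Tools for parametrising small fused-ring molecules (such as
    beta-lactam cores) in the CHARMM cosine-series dihedral convention.
    Predicts dihedral phase shifts (0 or 180 degrees) directly from an
    equilibrium geometry before any fitting, flags ambiguous cases and
    enumerates alternative assignments; fits dihedral force constants to
    torsion-scan energy profiles by non-negative least squares with
    multiplicities and phases held fixed, group-sequentially and with
    optional multiplicity augmentation; fits harmonic bond, angle and
    improper parameters from a Cartesian Hessian; and validates parameter
    sets by multi-start conformer search, GROMOS conformational clustering
    and RMSD against the reference geometry.  Includes readers and writers
    for a CGenFF-style CHARMM stream dialect with penalty annotations,
    XYZ/PDB geometries, torsion-scan tables and plain-text Hessians, plus a
    synthetic fixture generator with known ground-truth parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
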