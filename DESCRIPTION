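Package: gcreg
Title: Gouy-Chapman Charge-Regulation Analysis of Peptide Adsorption onto
    Anionic Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-consistent Gouy-Chapman (diffuse double layer) model of
    pH-sensitive peptide adsorption onto anionic lipid vesicles, coupling the
    Grahame equation, sodium counterion binding, and potential-modified
    Henderson-Hasselbalch charge regulation of titratable residues.  Includes
    reductions of fluorescence titrations to adsorption isotherms and
    Langmuir-type partition fits, zeta-potential conversions through the
    planar diffuse layer (Stokes-Einstein, Henry/Smoluchowski, shear-plane
    estimation), Hill-equation pKa analysis of per-residue protonation
    fractions from constant-pH molecular dynamics, and synthetic-data
    generators with known ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
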