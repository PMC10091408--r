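Package: helixion
Title: Ion Atmosphere and Helical Geometry Analysis for A-RNA Duplex Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the monovalent-ion atmosphere around nucleic acid duplexes
    and the global helical geometry of A-form RNA from structure ensembles.
    Reads single- and multi-model PDB files, computes surface-minimal-distance
    radial distribution functions with Monte-Carlo shell-volume normalisation,
    detects solvation-shell boundaries and time-averaged shell occupancies,
    per-residue and groove ion occupancies, and superposed 3D/2D ion density
    maps. Derives base-pair reference frames, a global helix axis, inclination
    and local step parameters (twist, roll, tilt, rise), backbone dihedrals and
    sugar pucker. Classifies base pairs by interacting edge (Watson-Crick,
    Hoogsteen, Sugar) and glycosidic orientation and tracks terminal base-pair
    fraying. Scores ensembles against NOE restraint tables with a normalised
    chi-square using asymmetric experimental errors. Includes ion-count
    planning for simulation boxes and a deterministic synthetic generator of
    A-RNA duplexes with two-shell ion atmospheres for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
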