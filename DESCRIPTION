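Package: cocryscreen
Title: Lattice-Energy Based Virtual Screening of Pharmaceutical Cocrystals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale crystal structure prediction (CSP) engine and a
    cocrystal coformer screening layer built on top of it. Candidate crystal
    packings of rigid and semi-rigid organic molecules are generated in common
    space groups by low-discrepancy sampling, relaxed by lattice-energy
    minimisation under an exp-6 (Buckingham) repulsion-dispersion model with
    Ewald-summed point-charge electrostatics, and de-duplicated with a
    COMPACK-style packing-similarity (RMSD_n) clustering. Conformation-dependent
    intramolecular energies and atomic charges are supplied by a reusable
    local-approximate-model (LAM) database tabulated over torsion grids from a
    pluggable conformational-energy oracle. Candidate coformers are ranked by
    the lattice-energy difference between the best predicted cocrystal and the
    best neat structures of its components, with an enthalpy-of-fusion
    correction for coformers that are liquid at the screening temperature, and
    classified by a go/no-go energy threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
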