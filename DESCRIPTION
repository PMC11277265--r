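Package: cgparam
Title: Coarse-Grained Cofactor Parametrization Toolkit for Martini 3
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building Martini 3 coarse-grained models of
    photosynthetic cofactors (carotenoids, xanthophylls, plastoquinone,
    chlorophylls, heme): atom-to-bead mapping and projection of atomistic
    ensembles, Boltzmann-inversion fitting of harmonic bonded parameters
    with constraint substitution and distribution-matching refinement,
    GROMACS-dialect topology (ITP) emission and parsing, Bennett
    acceptance ratio free-energy estimation with water/octanol log P
    composition, and validation analyses (electron density profiles along
    a bilayer normal, Kabsch RMSD/RMSF, Shrake-Rupley solvent-accessible
    surface area). Ships reference bead mappings for eight cofactors and
    seed-deterministic synthetic generators for all test inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
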