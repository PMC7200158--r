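Package: oligocount
Title: Oligomerization Equilibria, Filament Geometry and Single-Molecule
    Copy-Number Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analyses of DIX-domain self-association: an
    isodesmic (equal stepwise dissociation constant) oligomerization
    equilibrium solver that converts SEC-MALS number-average masses into
    dissociation constants, helical-symmetry arithmetic and an idealized
    coordinate builder for antiparallel double-stranded filaments, a
    single-molecule TIRF pipeline (rolling-ball background subtraction,
    spot detection by fixed-sigma Gaussian fitting, trajectory linking
    with gap closing, Gaussian-mixture intensity calibration) that counts
    fluorophores per diffraction-limited spot, bootstrap and rank-sum
    statistics for field-level fluorescence comparisons, and seeded
    synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
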