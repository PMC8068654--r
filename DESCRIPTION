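Package: ligandprobe
Title: Density-Based Discrimination of Sulfide and Dinitrogen Ligands in
    Metalloprotein Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether electron-density features at
    metal-cluster ligand sites are better explained by sulfide or by
    diatomic N2-derived ligands, developed around the FeMo cofactor of Mo
    nitrogenase.  Provides sphere-integrated density statistics with
    population z-scores, anomalous-map analysis, a real-space
    difference-density Z score for atom groups, anisotropy and geometry
    diagnostics, a synthetic Gaussian-atom map generator with known ground
    truth, and a desk-scale restrained/quantum-refinement energy
    combination with a pluggable region energy backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
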