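Package: fscq
Title: Local Map-to-Model Validation for CryoEM with FSC-Q
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local validation of atomic models against cryoEM density maps.
    Computes per-voxel local resolution by sliding-window Fourier shell
    correlation (FSC), both between the two half maps of a reconstruction and
    between the full map and a map simulated from the atomic model with
    electron-scattering form factors.  The difference of the two local
    resolution volumes (FSC-Q, in Angstrom) and its ratio to the half-map
    local resolution (FSC-Q_R) quantify how much of the model is supported by
    the reproducible signal in the data, flagging poorly fitted regions and
    local overfitting.  Scores are projected onto atoms, written into the
    occupancy column of a PDB copy, and summarised per residue.  Includes MRC
    volume input/output, soft-mask construction, a deterministic synthetic
    scene generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
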