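Package: trajprofiler
Title: Contact Fingerprinting and Density Analysis of Protein-Ligand
    Trajectory Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of multi-frame structural ensembles of homo-multimeric
    protein-ligand complexes, aimed at locating and characterizing lipid
    binding sites such as the phosphoinositide sites on TRP channels.
    Provides per-residue contact-frequency fingerprints against ligand
    headgroups with subunit averaging and differential selectivity
    classification between two ligand species, minimum-distance time series,
    Kabsch superposition and per-subunit ligand RMSD relative to the initial
    configuration, frame-averaged mass- or occupancy-weighted atomic density
    maps with OpenDX input/output and map-map correlation, water-bridge
    occupancy analysis, a seeded generator of C4-symmetric tetramer
    ensembles with known ground truth, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
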