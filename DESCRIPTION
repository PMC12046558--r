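Package: rhface
Title: Facial-Selectivity Analysis of Dirhodium Paddlewheel Carbene Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Geometric analysis of conformational ensembles of dirhodium
    tetracarboxylate-carbene (paddlewheel) complexes. Reads multi-model PDB
    and multi-frame XYZ trajectories with a role-annotation topology map,
    classifies the four carboxylate arms into alpha/beta (and ~90-degree
    rotated, "primed") states, computes the prochiral Re/Si face assignment
    of the trigonal carbene carbon and the ligand-carbene centroid distances
    d(Re) and d(Si), percent buried volumes, and turns the per-frame
    descriptor series into a kernel-density-based facial-selectivity
    prediction with rigidity and multimodality diagnostics. Includes a
    synthetic ensemble generator with planted conformer states, Markov state
    switching and Gaussian coordinate noise for validation, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
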