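Package: afmscan
Title: Simulated Atomic Force Microscopy Scanning of Biomolecular Structures
Version: 0.1.0
Authors@R:
    person("afmscan", "developers", email = "afmscan@example.org", role = c("aut", "cre"))
Description: Converts biomolecular structures and trajectories in PDB format
    into simulated atomic force microscopy (AFM) height maps using a
    hard-collision tip model (probe sphere capped by a cone). Includes
    rigid-body orientation and staging of structures, scanning-grid
    construction, closed-form tip-sample collision geometry, Gaussian-blur
    and resampling post-processing, AFM-style rendering, movie export for
    multi-model trajectories, Pearson image correlation against experimental
    AFM rasters, a synthetic-structure fixture generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
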