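Package: cellecon
Title: Whole-Cell Resource Allocation Modeling of Bacterial Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A coarse-grained whole-cell model of bacterial gene expression in
    which heterologous circuits, metabolic pathways and host processes compete
    for shared transcription and translation machinery. The package couples a
    simple metabolism (substrate import, tRNA charging) to quasi-steady-state
    competition of promoters for RNA polymerase and of mRNAs for ribosomes,
    with ribosome biogenesis from rRNA and r-protein, an alarmone-proxy
    regulation built on the charged/uncharged tRNA ratio, and growth set by
    total translational capacity. Supports single-cell, batch and chemostat
    culture modes; perturbation knobs for antibiotic sequestration of RNA
    polymerase or ribosomes, rRNA gene dosage, elongation and tRNA supply;
    isocost-line sweeps for two-reporter circuits; growth-law calibration by
    particle swarm optimization; and a genome-scale flux balance module that
    augments an SBML metabolic reconstruction with a protein translation
    demand and analyzes production capacity and flux variability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    pracma,
    yaml,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'cellecon-package.R'
    'AllClasses.R'
    'calibrate.R'
    'circuits.R'
    'cli.R'
    'config.R'
    'fba.R'
    'params.R'
    'rates.R'
    'rhs.R'
    'sbml.R'
    'simulate.R'
    'sweeps.R'
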