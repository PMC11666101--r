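Package: glycoshield
Title: Sequon Discovery, Glycan Conformer Ensembles, and Beta-Subunit
    Occlusion Analysis for Voltage-Gated Sodium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how isoform-specific N-linked glycans on
    voltage-gated sodium (NaV) channel alpha-subunits shield the channel
    surface and occlude beta-subunit binding sites. Discovers NX[S/T]
    sequons in isoform sequences, maps their conservation across an
    alignment, classifies missense variants by their effect on sequons,
    grafts linkage-labelled glycan trees onto asparagine sites, samples
    clash-free conformer ensembles by torsional Monte Carlo, converts
    ensembles into occupancy grids and per-region occlusion verdicts, and
    models beta1 immunoglobulin-domain trans dimers bridging opposed
    membranes, including a coarse bead-spring pulling routine and a
    closed-form maximum intermembrane distance. A synthetic-data module
    generates sequence families, toy channels, toy complexes, and toy Ig
    dimers so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: MAFFT (multiple sequence alignment)
Config/testthat/edition: 3
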