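Package: groomscan
Title: Grooming Ethograms, Bout Phenotypes, and Mixed-Model GWAS for Mouse Strain Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of mouse self-grooming in the open
    field and its genetics. Turns per-frame grooming probability streams into
    cleaned binary ethograms (consensus merging, temporal smoothing, a
    resting-posture heuristic on ellipse-fit shape change), quantifies
    inter-annotator agreement with a three-way disagreement taxonomy, segments
    ethograms into grooming bouts with pause/locomotion rules and derives a
    panel of bout-level phenotypes, clusters strains into grooming pattern
    types, selects environmental covariates by two-pass stepwise regression,
    runs a linear mixed model genome-wide association scan with
    leave-one-chromosome-out kinship, chip heritability, and a
    permutation-based significance threshold, clusters significant SNPs into
    quantitative trait loci by greedy linkage-disequilibrium clumping, and
    detects gene-trait modules in weighted bipartite association networks.
    Seeded synthetic-data generators emulate every input so the full pipeline
    runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
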