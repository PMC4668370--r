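Package: hmcdiff
Title: Permutation Enrichment and Differential Analysis of 5-Hydroxymethylcytosine Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for 5-hydroxymethylcytosine (5-hmC) pulldown
    sequencing (hMe-Seal) and TAB-seq data. Implements a tag-weighted
    permutation enrichment test of peak sets against genomic annotations
    (CpG islands, shores, promoters, gene bodies, transcription-factor
    binding sites), gene-level 5-hmC density quantification with percentile
    binning, integration with differential gene expression, metagene
    coverage profiles, replicate-consensus peak overlap at base and gene
    level, tumor/normal differential hydroxymethylation calls with
    expression concordance counting, and three-state (C / 5-mC / 5-hmC)
    quantification from bisulfite and TET-assisted bisulfite clone counts.
    A synthetic-data module generates genomes, peak sets, tag alignments,
    expression tables, matched cancer cohorts and clone-count tables with
    configurable planted structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
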