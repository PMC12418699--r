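Package: cenarch
Title: Centromere Architecture and Retrotransposon Chronology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying centromere evolution in repeat-rich plant
    genomes such as allopolyploid wheat. Delimits CENH3-enriched functional
    centromeres from ChIP/Input coverage, detects full-length LTR
    retrotransposons ab initio from their structural hallmarks (paired long
    terminal repeats, target-site duplications, TG...CA termini), dates each
    insertion from 5'/3' LTR divergence under the Kimura two-parameter model
    (age = K / 2r), classifies elements against a labelled family consensus
    library with a neighbor-joining tree, and provides the comparative
    statistics used in centromere evolution studies: region partitions,
    insertion-age distributions, exact Mann-Whitney U tests, dot plots and
    satellite monomer identity heatmaps. A synthetic-genome simulator with
    exported ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
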