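Package: convloss
Title: Genetic Dissection of Convergent Trait Loss in Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting repeated, independent losses of a binary
    morphological trait (such as plant prickles) across related species.
    Implements loss-of-function variant classification against gene models
    with a translate-the-mutant oracle, Mendelian segregation and
    duplicate-recessive epistasis tests for F2 populations, delta SNP-index
    bulked-segregant (QTL-seq) mapping with simulation-based confidence
    bands, cross-species co-expression conservation scoring by
    neighbor-voting AUROC, tissue-specificity (tau) scoring, Dollo and Fitch
    parsimony counting of independent trait losses, and collinear synteny
    chaining. A synthetic-data generator produces genomes, gene models,
    variants, F2 populations, bulk sequencing counts, expression compendia,
    and trait-mapped phylogenies with known ground truth, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
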