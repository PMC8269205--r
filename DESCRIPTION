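Package: ventlink
Title: CRISPR-Informed Virus-Host Networks and Viral Biogeography for
    Hydrothermal Vent Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to infer virus-host infection networks from CRISPR
    evidence in deep-sea hydrothermal vent metagenomes, and to analyse
    viral diversity and biogeography. Detects CRISPR repeat-spacer arrays
    in contigs, pools spacers by direct-repeat type, clusters viral
    contigs into vOTUs (greedy 95% identity / 80% coverage) and spacers
    by Markov clustering of an alignment-score graph, links metagenome
    assembled genomes (MAGs) to vOTUs via exact direct-repeat matches and
    bounded-mismatch spacer-protospacer matches, and computes relative
    abundance, diversity proxies, rarefaction, endemism statistics and
    compositional (clr) sample clustering with bootstrap support. A
    synthetic vent-community simulator with a planted infection network
    makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    vegan
Config/testthat/edition: 3
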