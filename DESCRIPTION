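Package: spacerlink
Title: CRISPR Spacer-Based Linking of Mobile Genetic Elements to Their
    Microbial Hosts in Time-Series Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to resolve CRISPR-mediated interactions between invasive
    mobile genetic elements (plasmids and bacteriophages) and their bacterial
    hosts from time-resolved metagenomic assemblies. The package clusters
    CRISPR spacers, repeats and flanking sequences into non-redundant
    elements, anchors CRISPR loci to metagenome-assembled genomes, detects
    protospacers on contigs, consolidates plasmid/phage predictor flags into
    mobile-element labels, normalises spacer abundances to counts per million,
    classifies spacer gain and loss events over time, builds global and
    time-point-resolved bipartite host-element interaction networks with
    Barber modularity and NODF nestedness, and fits randomised linear models
    of family-level community dynamics. A synthetic-community generator with
    planted ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
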