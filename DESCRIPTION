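Package: wgdkit
Title: Paleopolyploidy Inference from Gene Collinearity, Ks and Genome
    Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing whole-genome duplication (WGD)
    histories from comparative genomic data: detection of collinear
    (syntenic) gene blocks by rank-coordinate chaining, synonymous and
    nonsynonymous substitution rates (Ks, Ka) for collinear gene pairs via
    the Nei-Gojobori method with Jukes-Cantor correction, Ks-based
    classification of blocks into duplication and speciation events,
    polyploidy multiplicity inference from ortholog depth ratios,
    construction of event-related multi-genome homologous gene tables,
    post-polyploidy fractionation statistics with geometric run-length
    fitting, and Ks-peak fitting with lineage rate correction and
    molecular dating against a calibrated event.  Includes a three-genome
    simulator (shared hexaploidy, two speciations, one lineage-specific
    tetraploidy) that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    mclust,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
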