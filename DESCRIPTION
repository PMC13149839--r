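Package: codtcr
Title: Germline Annotation and Repertoire Analysis of Teleost T-Cell
    Receptor Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for annotating T-cell receptor (TR) gene segments in
    genomic sequence and for analysing expressed TR repertoires, built
    around the unusual locus architecture of Atlantic cod (Gadus morhua):
    recombination signal sequence (RSS) scanning with canonical and
    variant heptamer/nonamer motifs, D-gene detection from paired RSSs,
    functionality classification, V-subgroup clustering, translocon and
    mini-cluster delineation, IMGT-style nomenclature, and bootstrapped
    neighbour-joining phylogenies.  A V(D)J recombination simulator
    generates cod-like fixture loci and clonotype repertoires with full
    ground truth.  Repertoire statistics cover read filtering,
    rarefaction, D50, Shannon diversity, CDR3 length distributions,
    V-gene usage and correlations, replicate overlap with Kendall's
    tau-b, public/private CDR3 sharing, repertoire-size bounds, and
    inter-translocon recombination detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
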