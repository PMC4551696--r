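Package: csnannot
Title: Clinical Sequencing Nomenclature Annotation of Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transcript-strand-aware annotation of variant calls for clinical
    genomics. Indels are normalized to their most 3' position in the coding
    transcript, every variant receives a fixed Clinical Sequencing Nomenclature
    (CSN) string combining the nucleotide and protein-level description, a
    single consequence class from a 14-class priority ontology, a Sequence
    Ontology term and an impact category, and variants with alternative
    equivalent representations are flagged together with the annotation of the
    most 5' alternative. Reads VCF against an indexed FASTA reference and a
    GTF/GFF or tab-separated transcript database, and writes annotated VCF or
    a tab-separated table. Includes a deterministic synthetic fixture
    generator (reference genome, transcript models, variant calls) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    optparse,
    parallel
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
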