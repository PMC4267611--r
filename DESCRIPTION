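Package: esnvkit
Title: Expressed Single-Nucleotide Variant Filtering, Merging and
    Benchmarking for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-alignment toolkit for calling expressed single-nucleotide
    variants (eSNVs) from non-directional paired-end RNA-Seq. Parses
    samtools-mpileup text or VCF records into per-site read evidence,
    applies a coverage-dependent hard-filter battery (total and
    alternate-allele depth, alternate-allele fraction, strand-bias ratio,
    and a Mann-Whitney read-position rank-sum screen), merges filtered
    call sets from two or more aligners into confidence-ranked variants,
    classifies variants against a gene model and joins known-variant,
    deleteriousness and protein-domain tables, and benchmarks call sets
    against genotyping-array or exome-sequencing truth with
    expression-aware gating (precision, recall, F-score, ts/tv, zygosity
    concordance). A seeded simulator generates paired-aligner evidence
    with known ground truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
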