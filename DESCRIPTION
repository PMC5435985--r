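Package: rtdkit
Title: Construction and Quality Control of Reference Transcript Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building non-redundant reference transcript datasets
    (RTDs) from short-read transcript assemblies. Splice junctions are
    classified by terminal dinucleotide motif and filtered on unique-read
    support across samples; assembled transcripts are filtered on junction
    quality, antisense containment, unknown gene membership and low
    expression; filtered transcriptomes are merged step-wise with
    intron-chain based redundancy removal. The resulting RTD can be padded
    ("QUASI") or trimmed so that all transcripts of a gene share end
    coordinates, scored against U2/U12 splice-site position weight matrices,
    and translated from a gene-fixed AUG into a protein set that is digested
    in silico into a tryptic peptide database with isoform-uniqueness
    annotation. Alternative-splicing isoform ratios (AS/FS) computed from
    transcript quantifications can be validated against experimental
    peak-area measurements. A deterministic synthetic-data generator
    produces toy genomes, annotations, junction tables and quantification
    tables with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
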