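Package: bsamap
Title: Bulked Segregant Analysis Sequencing for Haploid Fungal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping binary traits in haploid (monokaryotic)
    fungal crosses by bulked segregant analysis sequencing (BSA-seq).
    Computes per-site pool statistics from a VCF with parental genotypes
    and pooled allele depths (SNP-index, Delta SNP-index, G statistic,
    Euclidean distance, two-tailed Fisher exact test), smooths them along
    the genome with a tricube kernel, calibrates 99% significance
    thresholds from a haploid null-pool simulation, intersects the four
    methods into consensus QTL intervals, and annotates candidate genes
    and coding variants (CDS splicing, translation, missense calls)
    inside them. A synthetic haploid-cross generator emulates a
    segregating monokaryotic population with a single fully penetrant
    causal locus and emits standard VCF/GFF3/FASTA/TSV files, so the
    whole pipeline runs end-to-end without external data. Segregation
    ratio chi-square utilities support the breeding-population stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
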