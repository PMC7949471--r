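Package: hlaumi
Title: UMI-Based Quantification of HLA Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies HLA gene- and allele-specific mRNA expression from
    UMI-tagged 5'-end RNA-seq reads. Reads are aligned to a per-sample
    personalized reference built from the individual's HLA genotype,
    discriminating polymorphic sites are discovered as high-entropy columns
    of per-gene multiple alignments, unique molecules (UMI groups, allowing
    one barcode mismatch) are assigned to alleles either uniquely or by a
    Bayesian per-site likelihood over phred error probabilities, and
    deduplicated molecule counts are normalized (counts per million for cDNA
    libraries, proportion scaling for targeted amplicon libraries). Includes
    derived allelic-imbalance and allelic-lineage summaries, a seeded
    read simulator with ground truth for validation, and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ShortRead,
    data.table,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
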