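Package: cannatype
Title: Chemotype and Genotype Classification of Cannabis sativa from
    Cannabinoid Ratios and THCAS/CBDAS Allele-Specific Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies Cannabis sativa samples into drug-type (chemotype I),
    intermediate-type (chemotype II) and fiber-type (chemotype III) from
    quantified THC and CBD contents via the log10(%THC/%CBD) statistic, with
    both fixed-cutoff and complete-linkage clustering classifiers.  Predicts
    the same classes from DNA by simulating allele-specific (ARMS-style) PCR
    assays on tetrahydrocannabinolic acid synthase (THCAS) and cannabidiolic
    acid synthase (CBDAS) coding sequences, coding band patterns into T/t and
    D/d allele symbols and composite genotypes (Td, TD, tD).  Includes ORF
    integrity analysis (premature stops, frameshift indels), neighbor-joining
    phylogenies of single and concatenated gene sets with column-resampling
    bootstrap, chemotype-genotype concordance summaries, and a synthetic
    panel generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
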