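Package: barcodekey
Title: DNA Barcoding Gap Analysis and Species-Diagnostic SNP Keys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distance-based species discrimination from aligned DNA
    barcode loci and construction of species-diagnostic SNP keys from
    genotyping-by-sequencing calls. Computes Kimura two-parameter
    pairwise distances with pairwise deletion, intraspecific and
    interspecific distance distributions (the barcoding gap), best-match
    and best-close-match identification tests, neighbor-joining trees
    with bootstrap support and monophyly-based discrimination scoring,
    nucleotide diversity and Tajima's D, Tassel-style SNP site filters,
    diagnostic-SNP screening and sample classification, and pairwise Fst
    between species. Includes a synthetic-data generator for
    multi-species barcode alignments and GBS-like genotype matrices with
    controllable gene flow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    vcfR,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
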