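Package: ksubmap
Title: Mapping-by-Sequencing via Pool-Specific K-mer Subtraction for EMS Bulks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulked-segregant mapping-by-sequencing for EMS mutants in
    polyploids without a reliable reference genome. Implements pool-specific
    k-mer subtraction between a phenotypically wild-type bulk and a mutant
    bulk, recruitment and de Bruijn assembly of allele-specific reads,
    homology and transposable-element filtering of scaffolds with an affine
    Smith-Waterman scorer, ungapped read mapping with zygosity-based
    candidate-site calling and MutMap-style SNP indexes, an RNA-seq
    fold-change/TPM screening step, and a synthetic allotetraploid
    bulked-segregant read simulator used to validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
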