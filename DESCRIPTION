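Package: mirseed
Title: Homology-Seeded Plant miRNA Discovery and Drought-Response
    Expression Analysis from Small RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of small RNA deep-sequencing libraries from crops
    without a sequenced reference genome. Provides adapter trimming,
    length filtering and read collapsing; annotation-based classification
    of reads into structural RNA categories; mismatch-bounded mapping of
    collapsed reads to a surrogate reference; excision of candidate
    precursor windows and energy-minimizing secondary-structure folding
    with stem-loop, star-strand, free-energy and G/C acceptance criteria;
    homology-based family naming against a reference set of mature
    miRNAs; transcripts-per-million normalization with the
    Audic-Claverie test for two-library count comparisons and a signed
    fold-change convention; complementarity-based miRNA target scanning
    with an expectation penalty score; and a fully seeded synthetic-data
    generator that plants hairpin precursors, per-condition fold changes
    and target sites so that every stage of the pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
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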