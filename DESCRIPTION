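Package: aglscan
Title: Discovery and Characterisation of PG-Rich GPI-Anchored Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterising small, secreted,
    proline/glycine-rich intrinsically disordered proteins (AGP-like
    proteins, "AGLs") from transcript, genomic and protein sequences.
    Provides six-frame open reading frame scanning with a PG-content
    filter, k-mer read baiting for targeted reassembly, composition and
    isoelectric-point profiling with signal-region handling (imported
    predictor calls or built-in heuristics), tandem-repeat detection with
    unit-consensus similarity scoring and biophysical zone classification,
    codon-usage tables over repeat regions, global pairwise alignment with
    region-partitioned identity and frameshift-gap reporting, a five-class
    candidate classifier, and a synthetic fixture generator that plants
    genes with known signals, introns and repeat arrays for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
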