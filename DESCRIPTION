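Package: metabar
Title: Taxonomic Assignment, Benchmarking and Barcode Resolution for
    DNA Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational core of an amplicon
    metabarcoding workflow aimed at meat and food authentication.
    Parses NCBI-style taxonomy dumps and answers lineage, last common
    ancestor and fractional consensus queries; filters tabular
    similarity-search (BLAST outfmt 6) hits and assigns read clusters
    a consensus taxon; builds thresholded per-sample compositions;
    benchmarks observed against expected compositions (precision,
    recall, F-beta, geometric-mean precision-recall, Euclidean
    distance, relative error, yield, splitting level) including an
    F2-optimizing detection-threshold sweep and seeded paired-end
    down-sampling; predicts the taxonomic resolution of a primer pair
    by in-silico PCR barcode extraction and pairwise-identity
    consensus analysis; and generates fully synthetic inputs
    (taxonomies, reference sequences, hit tables, FASTQ) for testing
    and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
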