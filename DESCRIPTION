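Package: xdense
Title: GA-Repeat and Binding-Site Density Analysis for X-Chromosome
    Dosage Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how dinucleotide-repeat expansion shapes
    the density of transcription-factor binding sites on sex chromosomes.
    Implements protein-binding-microarray (PBM) probe classification and
    two-Gaussian intensity mixtures, position weight matrix scanning with
    exact p-values computed by dynamic programming, minimal-motif
    flank-separation scans, k-mer plus DNA-shape ridge regression with
    cross-validated model comparison, maximal dinucleotide-repeat run
    detection with per-megabase X:autosome density ratios, peak
    nearest-neighbour clustering statistics with randomization
    normalization, metagene profiles, coverage enrichment, and seeded
    synthetic-data generators with recorded ground truth for closed-loop
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
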