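Package: kmerprimer
Title: Degenerate PCR Primer Design from k-mer Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Alignment-free design and assessment of degenerate PCR primers
    for functional-gene amplicon studies. Sequences of a target-gene FASTA
    database are decomposed into k-mers over a primer-length range;
    high-frequency k-mers are merged by overlap, and Hamming-distance-1
    variants are folded into IUPAC degenerate primers. The package computes
    GC content and annealing-temperature ranges, a nearest-neighbor hairpin
    self-folding free energy, in-silico amplification coverage and product
    lengths, off-target specificity, and covered taxonomy and phenotype
    groups. A synthetic database generator with planted conserved motifs
    provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
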