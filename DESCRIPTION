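Package: barcodegap
Title: Barcode-Gap Species Discrimination for Congeneric DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Threshold-based DNA-barcode species discrimination for
    congeneric taxa. Computes Kimura-2-parameter (K2P), p and Jukes-Cantor
    distances from aligned multi-FASTA loci under pairwise or complete
    deletion, collapses conspecific accessions into majority-rule consensus
    representatives, derives the maximum intra-specific distance threshold
    per locus or multi-locus concatenation, and reports percent species
    resolution (A - B) * 100 / A together with the unresolved species
    pairs. Includes a ground-truthed simulator of congeneric multi-locus
    datasets (star phylogeny, exact K2P substitution process, shared
    plastid haplotype pairs, partial locus availability) so the whole
    pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
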