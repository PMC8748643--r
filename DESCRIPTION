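Package: mitocomp
Title: Comparative Mitogenomics: Gene Order, Composition, Codon Usage and
    Intraspecific Diversity
Version: 0.1.0
Authors@R:
    person("Mitocomp", "Developers", email = "mitocomp@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal (primarily
    insect) mitochondrial genomes. Detects and counts gene-order
    rearrangements (transpositions, inversions, inverse transpositions)
    of signed circular gene orders against the ancestral insect
    arrangement, computes nucleotide composition statistics (AT content,
    AT/GC skew, sliding-window deviation profiles), classifies start and
    stop codons including incomplete polyadenylated stops, computes
    relative synonymous codon usage under the invertebrate mitochondrial
    genetic code, scans protein-coding genes for internal stop codons and
    single-nucleotide frameshift hypotheses, and calls SNPs and
    nucleotide diversity across conspecific mitogenome variants. Includes
    a seeded synthetic-mitogenome generator with ground-truth manifests
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
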