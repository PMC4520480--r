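Package: mitocomp
Title: Comparative Mitochondrial Genome Annotation Statistics and
    Supermatrix Construction
Version: 0.1.0
Authors@R:
    person("mitocomp", "developers", email = "mitocomp@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative characterization of annotated insect
    mitochondrial genomes: ingestion of GenBank flat files and plain
    feature tables, gene-name canonicalization against the 37-gene insect
    mitogenome vocabulary, gene-order and junction (overlap/spacer)
    statistics, start/stop codon classification including T/TA partial
    stops, strand- and codon-position-resolved nucleotide composition with
    AT/GC skews, codon usage tables, construction of concatenated
    phylogenetic supermatrices with codon-position partition schemes, and a
    seeded generator of synthetic annotated mitogenomes with ground-truth
    manifests for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
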