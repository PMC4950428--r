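Package: pancdbg
Title: Space-Efficient Compressed de Bruijn Graphs of Pan-Genomes with Search
Version: 0.1.0
Authors@R:
    person("pancdbg", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds the compressed de Bruijn graph of a pan-genome (the
    concatenation of several genomic sequences separated by '#' and
    terminated by '$') directly from an FM-index, without materializing the
    uncompressed graph. The graph is kept in an implicit, space-efficient
    form (one quadruple per node plus two marked bit vectors over the
    suffix array) from which the classical explicit representation
    (position and adjacency lists per node) can be derived by one backward
    walk per sequence. The FM-index also supports locating the node path
    that spells an arbitrary pattern of length at least k, and a document
    array answers which input sequences contain a pattern or node and how
    often. Includes a deliberately naive reference implementation
    (suffix sort, LCP, window-graph compaction) used as ground truth in
    the test suite, a synthetic pan-genome simulator, FASTA input,
    TSV/DOT/GFA1 exports and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
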