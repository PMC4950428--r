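# pancdbg

Compressed de Bruijn graphs of pan-genomes, built directly from an
FM-index, with pattern search.

## The problem

A *pan-genome* is the combined sequence content of many individuals or
strains of the same (or closely related) species. A natural graphical
summary is the **compressed de Bruijn graph of order k**: take one node
per distinct k-mer, connect two k-mers when they occur *consecutively* in
one of the sequences (not merely because they overlap k−1 symbols), and
merge every non-branching chain into a single node carrying a longer
string. Segments shared between strains collapse into single repeat
nodes; variation shows up as branching, so the shared/strain-specific
status of any substring — and its flanking context — can be read off the
graph.

`pancdbg` builds this graph for the concatenation

```
S = S¹ # S² # … # S^d $
```

of `d` sequences (separator `#`, sentinel `$`; each occurrence of `#` is
treated as a distinct symbol, so separators never take part in repeats)
**without ever materializing the uncompressed graph**. The construction
works on an FM-index of `S` — suffix array `SA`, Burrows–Wheeler
transform `BWT`, a wavelet tree with rank support, and the generalized
backward-extension step `getIntervals` — and keeps the graph *implicit*:

* node `G[id] = (len, lb, size, suffix_lb)` — the node's string is
  `S[SA[lb] .. SA[lb]+len−1]`, `[lb .. lb+size−1]` is its suffix array
  interval (so `size` = number of occurrences) and
  `[suffix_lb .. suffix_lb+size−1]` is the interval of its length-k
  suffix;
* two rank-enabled bit vectors over the suffix array: `B_r` marks the
  boundaries of every right-maximal k-mer interval, `B_l` marks
  non-right-maximal k-mers that precede a left-maximal k-mer. Node
  identifiers are pure rank formulas on these vectors, which is what
  makes search possible.

Construction runs three passes: (1) LCP values up to level k are
computed directly from the BWT (a 2-bit code per entry suffices) and the
right-maximal k-mer intervals plus `B_r`/`B_l` are derived in one scan;
(2) every seeded node is extended leftwards symbol by symbol with
`getIntervals`, stopping where a predecessor node ends (a `B_r` rank
test) and splitting where the string is left-maximal (a `B_l` rank gives
the new identifier); (3) optionally, one backward walk per sequence
turns the implicit form into the classical explicit representation
(`posList`/`adjList`/`StartNodes`), using the index shift
`SA[lb + (i − suffix_lb)] = SA[i] − (len − k)`.

Because the FM-index stays around, a pattern `P` (|P| ≥ k) can be
located in the graph: backward search finds the interval of `P`'s k-mer
suffix, an iteration of Ψ plus the `B_r`/`B_l`/stop-node tests finds the
node containing it, and the remaining symbols of `P` are consumed by
further backward search steps, emitting the node path. A document array
in a wavelet tree answers "which sequences contain this pattern/node,
and how often" with one range-distinct query.

## Worked example

```r
library(pancdbg)

tx <- encode_and_concatenate(c(strainA = "ACTACGTACGTACG"))  # S = ...$, n = 15
fm <- build_fm_index(tx)
mk <- kmer_marks(fm, 3)       # B_r ones at {2,4}; B_l ones at {9,12}
g  <- build_implicit(fm, mk)
g
#> implicit_cdbg: k = 3, 4 node(s) (1 right-maximal, 2 split, 1 stop)

for (id in 1:g$N) cat(sprintf("G[%d] = (len=%d, lb=%d, size=%d, suffix_lb=%d)  %-5s at %s\n",
  id, g$len[id], g$lb[id], g$size[id], g$suffix_lb[id],
  node_string(fm, g, id), paste(node_positions(fm, g, id), collapse = ",")))
#> G[1] = (len=4, lb=13, size=3, suffix_lb=2)  TACG  at 3,7,11
#> G[2] = (len=4, lb=5, size=1, suffix_lb=9)  ACTA  at 1
#> G[3] = (len=4, lb=7, size=2, suffix_lb=11)  CGTA  at 5,9
#> G[4] = (len=3, lb=6, size=1, suffix_lb=1)  CG$   at 13

res <- search_pattern(fm, mk, g, "ACGTACG")
res
#> pattern ACGTACG: node path [1 -> 3 -> 1], 2 occurrence(s)
search_occurrences(fm, res)
#> [1] 4 8
```

Reading the output: the repeat `TACG` occurs three times and is one
node; the unique prefix `ACTA` is the start node, `CG$` the stop node
(it owns the sentinel). The pattern `ACGTACG` enters node 1 (inside
`TACG`), crosses `CGTA` and re-enters `TACG`; its two occurrences start
at text positions 4 and 8.

The same pipeline scales to multi-sequence input from FASTA
(`read_fasta()`), conversion with `to_explicit()`, membership queries
with `build_document_array()` / `node_sequences()`, and exports to TSV,
DOT and GFA1. A CLI covering the whole pipeline is in `inst/cli/pancdbg`
(subcommands `simulate`, `index`, `build`, `explicit`, `search`,
`stats`).

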