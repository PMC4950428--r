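---
title: "Methods: implicit compressed de Bruijn graphs over an FM-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: implicit compressed de Bruijn graphs over an FM-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancdbg)
```

## Model

A pan-genome of `d` sequences is concatenated into
`S = S¹#S²#…#S^d$` over an ordered alphabet with `$ < # < ` all other
symbols (ascending byte order after uppercasing). Arbitrary byte
symbols are allowed; only `$` and `#` are reserved. Every occurrence of
`#` is treated as if it were a distinct character: separators can then
never be part of a repeat, each sequence ends in its own *stop node*,
and no graph node ever spans a sequence boundary. This is implemented
without enlarging the alphabet — purely by seeding the LCP computation
with one singleton interval per `#` occurrence instead of the joint
`#`-interval.

The de Bruijn graph of order `k` has a node per distinct k-mer of `S`
and an edge `(u, v)` when `u` and `v` occur *consecutively* in a
sequence. This is not the assembly graph: two k-mers overlapping `k-1`
symbols without occurring consecutively get no edge. Merging every
chain in which `u` is the only distinct predecessor of `v` and `v` the
only distinct successor of `u` yields the compressed graph.

Rather than storing node strings, `pancdbg` keeps one quadruple
`(len, lb, size, suffix_lb)` per node over the suffix array of `S`,
plus two bit vectors with plain (uncompressed) rank support:

* `B_r[i] = 1` iff `i` is the left or right boundary of the suffix
  array interval of a right-maximal k-mer. These intervals are exactly
  the lcp-intervals of lcp-value `k`, and they are pairwise disjoint,
  so membership of any interval `[i..j]` is decided by
  `rank₁(B_r, i)` being odd or `B_r[i] = 1`, and the node identifier is
  `⌊(rank₁(B_r, i)+1)/2⌋`.
* `B_l[i] = 1` iff the k-mer at `SA[i]` is not right-maximal, `i` is
  the right boundary of its interval, and the k-mer one text position
  to the right is a left-maximal repeat. Split-node identifiers are
  `rightMax + rank₁(B_l, i−1) + 1`.

Identifiers are therefore *computable from the index alone*, which is
what lets a pattern search land in the graph without any auxiliary
position-to-node map.

## Construction

1. **LCP levels from the BWT.** A breadth-first interval sweep over the
   wavelet tree (the `getIntervals` generalization of backward search)
   produces LCP entries in ascending order; running it only to level `k`
   and classifying entries as `<k / =k / >k` needs two bits per entry.
   The sweep starts from the per-occurrence separator singletons, which
   realizes the distinct-separator order.
2. **Marking.** One scan over the level array finds the maximal runs of
   entries `≥ k` (intervals of repeats of length `≥ k`). Runs containing
   an `= k` entry are right-maximal k-mer intervals: their boundaries go
   into `B_r` and a node `(k, lb, size, lb)` is seeded per interval, in
   ascending `lb` (hence lexicographic) order. For every run whose BWT
   range contains two distinct symbols (detected with a running
   last-difference index), the last occurrence `q` of each distinct
   non-separator symbol maps to `B_l[LF(q)] = 1`; marks that fall inside
   right-maximal intervals are then cleared.
3. **Left extension.** A FIFO queue holds node identifiers (seeds first,
   then one stop node `(1, j, 1, j)` per sequence, `j` being the suffix
   array index of the terminator). Each dequeued node is repeatedly
   extended with `getIntervals`: separator pairs are dropped (the node
   is a start node for those sequences); pairs whose `cω` k-prefix is
   right-maximal stop (a predecessor node ends there); a sole surviving
   pair of a singleton list extends the node in place (`lb ← i`,
   `len ← len+1`; `size` cannot change because `ω` is not left-maximal);
   any other surviving pair spawns a split node `(k, i, j−i+1, i)` —
   the returned interval is guaranteed to be the full k-mer interval —
   enqueued once.
4. **Explicit form (optional).** One backward walk per sequence,
   starting at the stop node of the last sequence, fills `posList` and
   `adjList` back to front, resolving each predecessor with the same two
   rank tests and hopping from a node's k-suffix interval to its full
   interval via `idx ← lb + (i − suffix_lb)`.

**Search.** For a pattern `P` with `|P| ≥ k` and no separators:
backward-search `P`'s k-mer suffix; find its node by iterating Ψ on the
interval until a stop-node (`left boundary ≤ d`), `B_r`, or `B_l`
marker fires; then consume the remaining symbols right to left with
single backward steps, crossing node boundaries via the same tests. A
document array (sequence number per suffix array position, stored in a
wavelet tree) turns any resulting interval into per-sequence occurrence
counts with one range-distinct descent.

## Design choices made where the design was open

* **Extension vs split.** A branch extends only when the *original*
  `getIntervals` list had exactly one element and that element survives
  the separator and right-maximality filters; if the original list had
  two or more elements, every surviving branch spawns a split node. A
  separator branch among the pairs counts toward left-maximality (the
  distinct-separator order makes the sequence-start predecessor a
  distinct symbol), which is exactly what makes sequence-initial k-mers
  head their own start nodes.
* **Direction of the suffix-interval shift.** The identity actually
  used and tested is `SA[lb + (i − suffix_lb)] = SA[i] − (len − k)`:
  entry `i` of the k-suffix interval maps to the *start* of the same
  occurrence of the full node string, `len − k` positions to the left.
  The extracted statement of the underlying lemma is ambiguous about
  the sign in this artifact's sources, so the identity was fixed by
  exhaustive verification on the worked example and random fixtures
  before being frozen into a regression test.
* **Stop-node layout.** Stop node `j` (the node ending with the
  terminator whose suffix sits at suffix array index `j ∈ 1..d`)
  receives identifier `rightMax + leftMax + j`; `j = 1` is the
  `$`-terminated last sequence. The explicit-graph walks chain
  `d, d−1, …, 1` by following each discovered `#` to its stop node, so
  prepending yields globally ascending position lists and visit-ordered
  adjacency lists without sorting.
* **Queue discipline** is FIFO. Identifiers come from rank formulas, so
  the result is a pure function of `(S, k)` regardless of order; FIFO is
  fixed for reproducible traces. A split identifier seen twice is not
  re-seeded (its record would be identical), bounding queue insertions
  by the node count.
* **`getIntervals` output order** is ascending alphabet order (the
  natural left-to-right wavelet tree leaf order), making every
  downstream list deterministic.
* **Separator-free restriction in the edge-count oracle.** The
  brute-force edge count classifies k-mer *strings* as node-enders;
  k-mers spanning a separator are excluded from the split-successor
  class, since under distinct-separator semantics such a k-mer is
  unique, occurs in no sequence, and a literal reading would count a
  nonexistent edge into each affected start node.

## Parameters

* `k` (k-mer length): the only modelling parameter. Must satisfy
  `2 ≤ k < min |S^j|`; anything else is a hard error, since stop/start
  nodes are undefined for shorter sequences. Small `k` (2–5) produces
  dense, highly branching graphs; larger `k` (20–31 in typical
  pan-genome work) produces long shared nodes. The test suite sweeps
  `k ∈ {2..5}` because desk-scale fixtures (20–200 bp) only contain
  repeats at small `k`.
* Simulation (`simulation_config()`): `base_length` 1000 bp,
  `num_sequences` 3, `substitution_rate` 0.01/bp, `indel_rate`
  0.001/bp with geometric lengths of mean 2. These mimic the order of
  magnitude of divergence between strains of one bacterial species —
  about 1% point divergence and roughly tenfold fewer short indels —
  which is the regime where a compressed pan-genome graph is
  informative: long shared nodes punctuated by variant bubbles.

## What the generator emulates, and what a green test establishes

`simulate_pangenome()` produces one uniform random base sequence and
`d−1` mutated copies (per-base substitutions to a different uniformly
chosen symbol; insertions/deletions of geometric length at the indel
rate). It emulates the *topological* structure of a strain-level
pan-genome: shared segments interrupted by point variants and small
indels. It does not emulate base composition bias, repeat families,
mobile elements, rearrangements, or horizontal transfer — so a green
oracle-equivalence run establishes algorithmic correctness of the
construction and search on realistic graph shapes, not performance or
biological fidelity on real genomes. For exactly this reason the test
suite mixes mutated-copy fixtures with fully independent random
sequences (worst case for branching density).

## Numerical and degenerate-input choices

* All coordinates are 1-based with closed intervals, matching the index
  tables the implementation is validated against; `lb > rb` encodes the
  empty interval. Everything is integer arithmetic — there are no
  floating-point tolerances anywhere in the package.
* Ties cannot arise: level runs are maximal and disjoint, marked
  intervals are disjoint, and the three node-marker tests (stop, `B_r`,
  `B_l`) are mutually exclusive by construction; their evaluation order
  (stop, then `B_r`, then `B_l`) is fixed for determinism.
* Degenerate inputs: a text with no length-`k` repeat yields
  `rightMax = leftMax = 0` and one chain node per sequence; a de Bruijn
  sequence collapses to a single stop node, which is also the worst
  case for the Ψ-iteration during node location (bounded by the longest
  node string). Patterns shorter than `k` or containing separators are
  rejected; patterns with symbols outside the alphabet return an empty
  result rather than an error.
* The production suffix array builder is vectorized prefix doubling
  (`O(n log² n)`); the independent reference is a naive quadratic sort.
  Both must agree exactly, and do, on hundreds of random texts.

## Known limitations

* Plain (uncompressed) bit vectors, rank blocks and wavelet trees only;
  entropy-compressed variants and semi-external BWT construction are
  out of scope, as is any parallelism.
* Pure-R data structures target desk-scale inputs (up to ~10⁵ symbols
  comfortably); the design mirrors structures that scale much further
  in succinct-library implementations, but this package does not claim
  those constants.
* Search is exact; approximate matching and patterns shorter than `k`
  are out of scope.
* The JSON container stores the sequences plus `SA`/`BWT` and re-derives
  rank structures on load (verifying the stored arrays against the
  rebuilt index); it favours portability and inspectability over load
  speed.
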