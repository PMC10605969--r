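---
title: "An implicit pan-genome de Bruijn graph on the bidirectional FM-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An implicit pan-genome de Bruijn graph on the bidirectional FM-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panbdg)
```

## The model

A pan-genome — a collection of `S` closely related genomes — is concatenated
into a single text `T` with `'%'` separators between sequences and a final
`'$'` sentinel, under the alphabet order `$ < % < A < C < G < T`.  The
colored compacted de Bruijn graph (ccdBG) of order `k` has one node per
unitig: a maximal non-branching chain of the distinct k-mers of `T` (k-mers
with a separation character anywhere but their last position are excluded).
Edges correspond to `(k+1)`-mers, one edge per occurrence, so the graph is a
multigraph; the strain of origin of every node occurrence (its "color") is
recoverable from its text coordinates rather than stored.

`panbdg` never materialises nodes or edges.  It stores:

* the **bidirectional FM-index** of `T`: the Burrows-Wheeler transforms of
  `T` and of its full reversal `T^r`, with rank tables and a sparse suffix
  array (factor `s_SA`, default 16, applied to both sides).  A partial match
  is a pair of synchronized suffix-array intervals and can be extended by
  one character to the left or right in O(1);
* a node vector `G` storing per node its length, multiplicity,
  `left_kmer` (left bound of the suffix-array interval of its leftmost
  k-mer) and `right_kmer_r` (left bound of the reverse-side interval of its
  reversed rightmost k-mer);
* bit vectors `B` and `B_r` with rank support, marking — at the
  lexicographically largest suffix prefixed by the k-mer — every node's
  rightmost k-mer (plus checkpoints, below) and every node's reversed
  leftmost k-mer respectively;
* the maps `IDmap` (rank in `B` to node id and offset) and `IDmap_r`
  (rank in `B_r` to node id).

With these components, identifying the node of an extreme k-mer is a rank
plus a table lookup; jumping to the neighbor reached by prepending or
appending a character is one O(1) FM extension followed by such a lookup;
and jumping to a predecessor through a *specific* edge is one LF step from
the occurrence row `left_kmer + edgeOffset`.  All navigation is therefore
constant time.

### End nodes

Each of the `S` sequences contributes a distinct *end node*.  We concretise
end nodes as exactly the k-mer whose last character is the sequence's
separator (`len = k`): separator k-mers act as barriers during compaction
and are never merged, which also keeps two sequences with identical tails
distinct (each end node has multiplicity 1 and points at its own suffix
row).  An end node's rightmost k-mer is its cyclic extension starting at
the separator (e.g. `"$CT"`, `"%AT"` in the worked example); the
corresponding successor edges wrap into the following sequence and emerge
naturally from the FM-index mechanics, because the BWT encodes the cyclic
predecessor of every row.  These cyclic edges are traversable (the alphabet
loop of the neighbor jumps includes the separators by default) but excluded
from subgraph exports unless requested.

### Compaction rule

Two adjacent k-mers `u -> v` are merged only when the number of `u -> v`
edge occurrences equals both the occurrence count of `u` and that of `v` —
i.e. every occurrence of `u` is followed by `v` and every occurrence of `v`
is preceded by `u`.  This is slightly stricter than "unique successor /
unique predecessor" on distinct neighbors: a k-mer that also occurs at a
sequence start (where it has no incoming edge occurrence) starts its own
unitig.  The stricter rule guarantees that every occurrence of every
constituent k-mer is an occurrence of its unitig, which the whole implicit
representation relies on: node multiplicities equal suffix-array interval
widths, and every k-mer has a unique `(node, offset)` position.

### Checkpoint k-mers

Resolving an *arbitrary* (non-extreme) k-mer to its node naively requires
shifting the k-window through the node until an extreme k-mer is reached —
up to O(n) steps for long nodes.  For a finite checkpoint sparseness
`s_cp`, extra bits are set in `B` for every separator-free k-mer at node
offsets `j * s_cp` (j = 0, 1, ...) strictly below the rightmost offset, and
`IDmap` gains the matching `(id, offset)` rows.  Lookup then walks the
window leftward by LF steps from the lexicographically largest row of the
k-mer's interval until a marked row is hit; the walk is bounded by
`s_cp - 1` steps and — because offset 0 of every non-end node is marked —
provably terminates *inside* the node.  The query's offset is the stored
offset plus the number of steps.  In the worked example (`k = 3`,
`s_cp = 2`) exactly three checkpoint bits appear, at rows 13, 11 and 16.

Two boundary cases are handled outside the walk.  A k-mer ending in a
separator is the offset-0 k-mer of an end node and is resolved directly
from its text position.  With checkpoints disabled (`s_cp = Inf`, the
baseline bit vector) the leftward walk would leave the node before meeting
a mark, and once it crosses a branch point the row is no longer the
lexicographically largest of its k-mer interval, so marks can be missed
silently; `find_id()` therefore walks *rightward* (inverse LF) toward the
rightmost k-mer, which is always marked.  Within a unitig both walks
preserve "largest row", because all occurrences of an interior k-mer share
their continuation.  The rightward walk is O(node length); that cost is the
reason checkpoints exist.

## Approximate pattern matching

All occurrences `O` of a read `P` with edit distance `ED(O, P) <= K`
(substitutions and indels, `K <= 4`) are found losslessly with **search
schemes**: `P` is cut into `p` contiguous parts (uniform lengths, remainder
leftmost); a search `(pi, L, U)` processes the parts in `pi` order —
which must grow the processed span contiguously, enabled by the
bidirectional index — under cumulative lower/upper error bounds `L`/`U`
checked at part boundaries.  A scheme is a set of searches covering every
distribution of at most `K` errors over the parts; `validate_scheme()`
checks coverage by enumeration.  Built in are the pigeonhole schemes for
`K = 0..4` and the three-search two-error scheme of Kucherov and
colleagues; other schemes (e.g. published constructions for `K = 3, 4`)
load from a plain-text file (`p K` header, then `pi L U` digit triplets
per line).

Execution anchors a banded dynamic-programming alignment at every part
boundary: within a part, candidate occurrences are spelled character by
character over A/C/G/T through FM extensions while a DP row tracks the edit
distance of the spelled segment against the part (rows are pruned once
their minimum exceeds the current upper bound — an Ukkonen-style cutoff
that plays the role of an explicit 2K+1 band); every attainable
final-column value within `[L, U]` branches into the next part.  Because an
optimal alignment of any true occurrence induces a per-part error
distribution that some search covers, that occurrence is spelled along some
branch with exactly its minimal edit distance; duplicates from other
branches and searches are collapsed per distinct substring keeping the
minimal distance.  Occurrences never contain separation characters: a
match cannot span two sequences.

An occurrence at least `k` long maps to a unique node walk: the first node
comes from `find_id()` on any k-mer of `O` (the walk is extended leftward
first when seeded mid-string), after which the path jumps directly from
node end to node end, reading one boundary character of `O` per successor
jump — no re-matching.  Occurrences shorter than `k` are resolved by
enumerating all existing k-length extensions of their range and
deduplicating the implied start positions; windows ending in a separator
contribute one position per end node sharing that window.  Text
coordinates come from suffix-array locates; redundant text occurrences are
filtered per locus (same query, strand and sequence, transitively
overlapping intervals) keeping minimal edit distance, ties to the longer
then leftmost occurrence.  The brute-force scanner
`brute_force_occurrences()` — an FM-free banded scan of every text
position — is the independent reference for all of this in the test suite.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 25 | k-mer size; graph resolution (21 and up is typical for bacterial pan-genomes; the worked example uses 3) |
| `s_SA` | 16 | suffix-array sparseness; locate cost is up to `s_SA - 1` LF steps per occurrence |
| `s_cp` | 128 | checkpoint sparseness; node lookup cost is O(`s_cp`), memory grows as bits plus map rows per checkpoint; `Inf` disables |
| `K` | 0..4 | maximum edit distance for read alignment |

## The synthetic generator

`generate_pan_genome()` emulates a small pan-genome of closely related
strains: strain 0 is uniform random DNA; each further strain applies seeded
substitutions (default rate 0.005 per site, the order of divergence of
closely related bacterial isolates) and short indels (rate 0.001, length at
most 3).  Mutations avoid the first and last 25 bases of each strain so
end-node bookkeeping never interacts with truth loci.  `sample_reads()`
draws error-free substrings and plants 0..`planted_errors` edits, recording
the origin.  The generator captures what the data structure is sensitive to
— shared unitigs, bubbles, repeats arising by chance, known truth — but not
base-composition bias, structural variation, or realistic sequencing error
profiles; passing tests demonstrate algorithmic correctness, not robustness
to those properties of real data.

## Numerical and design choices

* **Canonical node ordering.**  Identifiers are assigned by decreasing
  multiplicity, ties by increasing `left_kmer`; end nodes occupy the last
  `S` slots in the order of their separator suffix rows.  Any ordering is
  admissible as long as the maps agree; this one assigns the worked
  example's identifiers deterministically, which the test suite exploits.
* **Rank tables.**  Full cumulative character-count tables (one row per
  text position) rather than sampled blocks: identical semantics, simplest
  O(1) rank at desk scale.
* **Edge identity for specific-edge jumps.**  The predecessor-side edge
  label is defined as the relative row within the predecessor's
  rightmost-k-mer interval; with it, enumerating `edgeOffset = 0..mult-1`
  over all nodes enumerates every edge exactly once, which the subgraph
  edge listing relies on.
* **Locus equivalence for filtering** is the transitive-overlap rule
  described above; strands are reported separately.
* **Coordinate assignment in the neighbor-variant scan**: a node is
  "unambiguously positioned" when its substring occurs exactly once in the
  designated reference sequence; the candidate coordinate is that
  occurrence's position plus the number of predecessor jumps walked.
* **Degenerate inputs.**  Sequences shorter than `k` are rejected;
  unbranching cycles (possible only in pathological texts) are broken at an
  arbitrary k-mer; `'N'` bases are replaced by a seeded random nucleotide at
  FASTA read time, with the seed recorded in the index metadata.

## Problem sizes used in validation

The packaged validation suite runs entirely on synthetic data: the 20-
character worked example for table-level fidelity; 50 seeded pan-genomes of
2–5 strains (roughly 5–20 kb of concatenated sequence) with 100 reads of
70 bp each for losslessness, the maximum edit distance cycling over 0..4
across genomes (ten genomes per value); and pan-genomes around 1–4 kb for
graph-oracle equivalence at `s_cp` in {1, 2, 8, Inf}, node-path spelling
and checkpoint invariance.  These sizes exercise every code path —
branching nodes, repeats, bubbles, sequence boundaries — while keeping the
suite fast; the data structure itself has no further scale-dependent
behavior beyond memory.

## Known limitations

* `K` is capped at 4; gapped/clipped alignment and SAM output are out of
  scope, as are paired-end protocols.
* The graph is not bidirected: a k-mer and its reverse complement are
  distinct nodes.  Reads are matched on both strands instead.
* Character jumps through a *separator* resolve to a single end node even
  when several sequences share an identical tail k-mer (the rank lookup
  returns one row); specific-edge enumeration and short-occurrence
  resolution handle the ambiguity correctly, and traversal restricted to
  A/C/G/T is unaffected.
* The explicit construction is O(n k) time and memory and is meant for
  desk-scale pan-genomes (up to a few hundred kilobases comfortably), not
  for human-scale collections.
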