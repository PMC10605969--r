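# panbdg

An implicit, memory-conscious **colored compacted de Bruijn graph (ccdBG)**
for pan-genomes, built on a **bidirectional FM-index**, with constant-time
graph navigation, checkpoint-accelerated k-mer→node lookup, symmetric
subgraph extraction and export, and **lossless approximate read matching**
under edit distance using search schemes.

## Who is this for

Researchers analyzing collections of closely related genomes (bacterial
strain panels, multiple assemblies of one species) who want, in one
structure: (i) a graph view of the pan-genome whose topology exposes shared
and divergent regions, (ii) *exhaustive* read alignment — every occurrence
within edit distance `K ≤ 4`, reported both as a **node path in the graph**
and as **coordinates in the underlying sequences** — and (iii) the ability
to extract and visualize any neighborhood of interest.

## The data structure

The `S` genomes are concatenated as `T = seq_0 % seq_1 % ... $` (alphabet
`$ < % < A < C < G < T`). On top of the bidirectional FM-index of `T`
(BWT of `T` and of its reversal, sparse suffix arrays with factor
`s_SA`), the graph is represented implicitly by:

* a node vector `G[id] = (len, mult, left_kmer, right_kmer_r)` — each
  unitig ω is recovered as `T[SA[left_kmer], SA[left_kmer]+len[`, never
  stored;
* bit vectors `B` / `B_r` marking, at the lexicographically largest suffix
  with that prefix, every node's rightmost k-mer (plus every `s_cp`-th
  "checkpoint" k-mer) and every node's reversed leftmost k-mer;
* rank→identifier maps `IDmap` (with per-entry node offsets) and `IDmap_r`.

A rank on `B`/`B_r` identifies the node of an extreme k-mer in O(1);
prepending/appending a character jumps to a neighbor in O(1); an arbitrary
k-mer resolves to its `(node, offset)` in O(`s_cp`) LF steps. Reads are
matched losslessly with search schemes (pigeonhole `K = 0..4`, the
Kucherov 2-error scheme, or schemes loaded from file), and every
occurrence maps to a unique node walk plus per-sequence coordinates.

## Worked example

The two-strain toy pan-genome `T = "CTATGTC%ATATGTTGGTC$"`, `k = 3`:

```r
library(panbdg)
txt <- pan_genome_text(c("CTATGTC", "ATATGTTGGTC"))
idx <- build_index(txt, s_SA = 1)
g   <- build_graph(idx, txt, k = 3, s_cp = 2)
g
#> ccdbg: k = 3, |V| = 7 (2 end nodes), 3 checkpoint k-mers, s_cp = 2
```

Seven nodes: `GTC`, `TATGT`, `ATA`, `CTA`, `GTTGGT` and the end nodes
`TC$`, `TC%`. Exact matching keeps synchronized intervals over both suffix
arrays, and any k-mer resolves to its node:

```r
match_exact(idx, "ATG")
#> bd_range: SA[3,5[  SA^r[9,11[  (width 2)
find_id(g, idx, match_exact(idx, "TTG"))   # one LF step to a checkpoint
#> $id: 4    $offset: 1                     # "TTG" sits in GTTGGT at offset 1
```

Lossless matching of read `ATGTC` with one error, mapped to coordinates
and to the graph:

```r
occ <- approximate_match(idx, "ATGTC", K = 1)
tx  <- do.call(rbind, lapply(seq_len(nrow(occ)), function(i)
  to_text_occurrences(idx, txt, occ[i, ], query_id = "read1")))
filter_redundant(tx)
#>   query_id strand seq_index seq_name start length ed
#> 1    read1      +         0    seq_0     2      5  0
#> 2    read1      +         1    seq_1     2      5  1
find_node_path(g, idx, occ[2, ])
#> graph_occurrence: path [1,0], start_offset 1, len 5, ED 0
```

The exact hit (`seq_0`, position 2, edit distance 0) spells `TATGT → GTC`;
the second locus (`seq_1`, position 2, `ATGTT`) is one substitution away.
Neighborhoods export as DOT, GFA 1.0 or a TSV edge list:

```r
cat(export_subgraph(extract_subgraph(g, idx, 1, 1), g, idx, "tsv"))
#> from_id  to_id  multiplicity
#> 1        0      1
#> 1        4      1
#> 2        1      1
#> 3        1      1
#> 4        0      1
```

A command-line front-end (`inst/scripts/panbdg-cli.R`) wraps the same
functions as `build`, `align`, `subgraph` and `synth` subcommands; the
`synth` command generates seeded toy pan-genomes and reads with recorded
ground truth.

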