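# overtrie

All-pairs suffix-prefix (APSP) overlap detection for DNA reads, built on a
compact prefix trie.

## What it is for

The overlap stage of overlap-layout-consensus genome assembly needs, for
every ordered pair of reads (S_i, S_j), the longest suffix of S_i that
equals a prefix of S_j — the edge set of the overlap graph. `overtrie`
computes exactly that for read sets over {A,C,G,T}: it indexes the k reads
in a compact prefix trie (radix trie) of at most 2k nodes, keeps the text
itself in 2 bits per base, builds in O(n) character comparisons for total
length n, and enumerates overlaps in O(k·l²) for maximum read length l.
It is aimed at anyone who needs an exact, self-contained overlap finder:
assembler prototyping, teaching, or as a reference to validate faster
heuristic overlap detectors against.

The core ideas:

* Each trie node stores a collapsed chain as a *length* only; chain
  characters are resolved from the encoded text via the node's
  representative read, so the index size is independent of n.
* Nodes carry the interval [r1, r2] of lexicographic read ids sharing the
  path prefix; a suffix that survives a walk overlaps every read in the
  final node's interval at once.
* Construction works on sorted input (intervals maintained inline) or
  unsorted input (shape first, then one DFS relabeling pass) — both give
  node-for-node identical trees.
* Optional containment prefiltering removes duplicate, prefix-contained and
  suffix-contained reads; four work-partitioning strategies (equal count,
  share threshold, dynamic chunks, greedy least-loaded) split the overlap
  workload across workers without changing the output.

## Worked example

The five reads AAGGG, ACTTT, AGGCT, GCCAC, TCCGC:

```r
library(overtrie)
rs  <- sort_reads(read_set(c("AAGGG", "ACTTT", "AGGCT", "GCCAC", "TCCGC")))
tr  <- build_sorted(rs)
tr
#> compact prefix trie: 7 nodes over k = 5 reads (n = 25 bases)
res <- find_overlaps(tr, min_len = 1, mode = "longest_only")
res$records
#>   query_id target_id length start_pos query_orig target_orig
#> 1        1         4      1         5          1           4
#> 2        2         5      1         5          2           5
#> 3        3         5      1         5          3           5
#> 4        4         2      2         4          4           2
#> 5        5         4      2         4          5           4
```

Seven nodes: the root, one chain-0 branching node grouping the three
A-reads, and five leaves. The records are the five nonzero entries of the
longest-overlap table: e.g. the last line says the suffix of read 5 (TCCGC)
starting at position 4 — "GC", length 2 — equals the prefix of read 4
(GCCAC), and no longer suffix of read 5 does. `overlap_matrix(res)` returns
the same information as a k×k matrix with 0 for "no overlap".

Synthetic inputs with known answers:

```r
g  <- generate_overlapping_reads(genome_len = 2000, k = 60,
                                 read_len_range = c(40, 120), seed = 42)
tr <- build_unsorted(g$read_set)
res <- find_overlaps(tr, min_len = 15)   # all matches of length >= 15
```

`g$truth` holds the longest true overlap per ordered pair, computed by
direct string comparison — handy as an independent check
(`brute_force_apsp()` and `verify_against_oracle()` do this
systematically).

## Command line

```sh
inst/cli/overtrie simulate --overlap-mode --genome-len 5000 --k 200 --seed 1 -o reads.fa
inst/cli/overtrie run reads.fa --min-len 30 --output-mode 2 -o overlaps.tsv
inst/cli/overtrie verify reads.fa --min-len 15
```

`run` writes a TSV (`query<TAB>target<TAB>overlap_length` with a `#` summary
header); `--output-mode` is 0 (count only), 1 (longest per pair) or
2 (all matches). `--no-sort` selects the relabeling construction,
`--workers`/`--strategy` select a partitioning plan, `--filter-contained`
enables the containment prefilter. `verify` exits nonzero if the trie path
ever disagrees with the brute-force oracle.

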