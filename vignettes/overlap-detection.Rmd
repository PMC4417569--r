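---
title: "Finding all-pairs suffix-prefix overlaps with a compact prefix trie"
author: "overtrie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding all-pairs suffix-prefix overlaps with a compact prefix trie}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overtrie)
```

## The problem

Overlap-layout-consensus assembly of a shotgun-sequenced genome starts by
computing, for every ordered pair of reads $(S_i, S_j)$, the longest suffix
of $S_i$ that equals a prefix of $S_j$ — the all-pairs suffix-prefix (APSP)
problem. With next-generation sequencing the inputs are millions of short
(50–1000 bp) reads over $\Sigma = \{A, C, G, T\}$, so both the index
structure and the text representation have to be small: `overtrie` keeps the
text in 2 bits per base and indexes the $k$ reads in a compact prefix trie
with at most $2k$ nodes, independent of the total length $n$.

## The data structure

Every read is a root-to-leaf path in a trie of all read prefixes. Unary
chains are collapsed: a node stores only the *length* of its chain
(`chain_len`), and the chain's characters are recovered on demand from the
2-bit text through the node's representative read — the read whose
lexicographic id equals the node's interval lower bound. Each node carries
the interval $[r_1, r_2]$ of the ids of all reads that share the prefix
spelled by the path to it. Because ids are lexicographic ranks, that set of
reads is always contiguous, which is what makes reporting matches O(1) per
target: a suffix that survives a walk down the trie overlaps *every* read in
the final node's interval.

Construction inserts reads one at a time, comparing characters against the
implicit chain. A mismatch inside a chain splits the node in two and hangs a
fresh leaf off the upper part; a mismatch at a node boundary opens a new
branch. Each consumed character costs one comparison, so construction is
O(n) — the test suite asserts the comparison counter stays below $2n$.

Two construction orders are supported and produce node-for-node identical
trees:

* **sorted** (`build_sorted`): reads are radix-sorted first; intervals can
  then be maintained inline, because each new read extends interval upper
  bounds along its path.
* **unsorted** (`build_unsorted`): the shape is built in file order with
  intervals ignored; a single depth-first pass (`relabel_intervals_dfs`),
  visiting children in A < C < G < T order, then assigns consecutive ids —
  reads terminating at a node first, then its subtrees. Exact duplicates are
  pooled per node in a registry during insertion and receive consecutive
  ids, which also recovers the stable lexicographic permutation of the
  input.

### Reads contained in other reads

The classical picture — every string is a leaf, every internal node has at
least two children — silently assumes no read is a prefix of another. That
assumption fails exactly when containment filtering is off, which is the
default operating mode here. Rather than forbid such inputs, each node
carries `n_end`, the number of reads ending exactly there: those reads are
lexicographically smallest among the subtree and occupy the low end
$[r_1, r_1 + n_{end} - 1]$ of the interval, with the children tiling the
remainder. On a prefix-free input this reduces to the textbook structure
(`n_end > 0` only at leaves), and `validate_trie()` checks the generalized
invariants: interval tiling with no gaps, the two-children rule for
non-terminal internal nodes, terminal count = distinct sequences, and the
$2k$ node bound.

## Overlap enumeration

For each query read of length $l$, every proper suffix is walked down the
trie, longest first (start position 2, 3, ...), skipping suffixes shorter
than the minimum overlap length $\ell$. Three outcomes are possible: the
suffix is exhausted (inside a chain or at a node boundary) and overlaps
every id in the current node's interval; a chain character mismatches; or
the required branch is absent. The per-read cost is at most
$l(l+1)/2 + l$ comparisons, giving $O(k\,l^2)$ overall — the quadratic
per-read bound is asserted in the tests.

Three output modes mirror what a consumer needs: `all_matches` streams one
record per matching (pair, suffix length); `longest_only` keeps the first
(hence longest) match per ordered pair and can expose the $k \times k$
length matrix; `none` only counts (the match count of a $k$-read instance is
$O(k^2)$, so large runs should not materialise records at all). The matrix
is refused above a configurable cap (default 20 000 reads) because it alone
costs $O(k^2)$ memory.

Decisions worth making explicit:

* Suffix enumeration starts at position 2, so a read wholly equal to
  another's prefix is never reported as an overlap — that situation is
  *containment* and belongs to the filter below.
* Self pairs are suppressed by default (`include_self = TRUE` re-enables
  them).
* A suffix exhausted mid-chain reports the current node's interval: all
  descendants share the consumed prefix, so the answer is identical to the
  boundary case.

## Containment prefiltering

In assembly practice, reads equal to a prefix or a suffix of another read
are redundant. The filter detects all three cases on the built trie:

* *prefix-contained*: the read terminates at a node that still has children;
* *duplicate*: several reads share a terminal node — the copy with the
  smallest original index survives;
* *suffix-contained*: detected during suffix walks — a suffix exhausted
  exactly at a terminal node boundary equals the full string of the reads
  ending there.

Removed reads are excluded from overlap output as queries and as targets by
masking at emission time; rebuilding the trie is unnecessary because
removing reads never changes whether a surviving suffix matches a surviving
prefix. The test suite checks this equivalence directly (filter-then-mask
equals rebuild-from-survivors), plus agreement with a brute-force
containment oracle and idempotence. Substring containment at internal
offsets (neither prefix nor suffix) is out of scope. Filtering is off by
default.

## Partitioning work across workers

The overlap stage parallelises by read: a read is never split across
workers. Since processing a read of length $l$ costs about
$W_S = l(l+1)/2$ comparisons, plans can balance estimated work rather than
read counts. Four strategies are provided:

1. `partition_equal_count` — contiguous blocks of near-equal read counts;
2. `partition_by_share` — reads are assigned in id order to the current
   worker until its accumulated $W_S$ *reaches* the optimal share
   $\sum W_S / p$; "reaches" is implemented as $\ge$, the reading under
   which the six-read worked example (works 6, 10, 10, 6, 6, 10, share 16)
   lands exactly two reads on each of three workers;
3. `dynamic_chunks` — a shared-pointer chunk dispenser (default 1024 reads
   per chunk); the plan form assigns chunks round-robin, a deterministic
   serial stand-in for the concurrent execution;
4. `greedy_assign` — each read goes to the currently least-loaded worker,
   ties to the lowest index; the classical bound
   $\max y - \min y \le \max W_S$ is property-tested.

Construction itself parallelises by first character(s):
`build_partitioned` groups reads by their first 1 or 2 bases (a read
shorter than the grouping depth is grouped by its full prefix). Groups are
disjoint by construction, so group-by-group insertion touches disjoint
subtrees and needs no coordination; the compact-trie shape is canonical in
the string set, so the merged tree is node-for-node identical to the single
build — asserted structurally on every test instance. All correctness tests
execute plans serially; parallel execution is an optional layer the plans
are designed for, not a correctness ingredient.

## Synthetic data

Two generators define the test conditions:

* `generate_random_reads(n, k, seed)` — k reads with lengths forming a
  uniform random composition of n (k−1 distinct cuts), bases i.i.d. uniform.
  This emulates a random benchmark input; true long overlaps are
  vanishingly rare in it, which is realistic for a *negative* control but
  exercises mostly the no-match paths.
* `generate_overlapping_reads(genome_len, k, read_len_range, seed)` —
  shreds a uniform random genome at random offsets so genuine suffix-prefix
  overlaps exist; it returns a truth table of the exact longest overlap per
  ordered pair, computed by direct string comparison, independent of the
  trie.

Neither generator models sequencing error, reverse-complement orientation,
quality values, or biased base composition, so passing tests demonstrate
exact-match correctness, not robustness to noisy reads — inexact and
reverse-complement overlaps are out of scope throughout.

The differential battery runs 104 seeded instances (read counts up to 500,
lengths 20–200, minimum overlap cycling through 1, 5, 15, 30; alternating
random and shredded inputs) and checks, on each: record-exact agreement
with the brute-force oracle, structural identity of sorted, unsorted and
prefix-partitioned construction, and identity of the overlap set under all
four work plans at a random worker count. A separate scale run (10^7 bases
in 10^5 reads, minimum overlap 30, counting mode) exercises the same code
path at assembly-like volume on one worker; both sizes were chosen so the
whole suite stays comfortably interactive.

## Numerical and degenerate-input choices

* Positions, ids and intervals are 1-based and inclusive everywhere in the
  interface.
* Children are a fixed 4-slot structure indexed by base; every traversal
  iterates A, C, G, T, making DFS relabeling and record order
  deterministic. Records arrive in (query id, suffix start, target id)
  order.
* The default minimum overlap length is 30, the conventional choice for
  short-read overlap detection; 1 is the minimum accepted.
* Reads with characters outside ACGT cannot be 2-bit encoded; the FASTA
  reader warns and skips them (strict mode errors). Empty inputs error
  early.
* The work estimate $W_S$ and comparison counters are kept as doubles in R
  (they exceed 32-bit range at assembly scale); encoded text offsets are
  limited to $2^{31}-1$ total bases.
* Ties in `greedy_assign` go to the lowest worker index; duplicate reads'
  ids preserve input order (stable sort and registry order agree).

## Limitations

* Exact matching only — no mismatches, indels, or reverse-complement
  overlaps.
* One text, in memory: no streaming or gzip input.
* The longest-only matrix is dense; for large k use `all_matches` (stream)
  or `none` (count).
* Work partitioning models comparisons, not cache effects; plans are
  deterministic and therefore reproducible, but not measured against wall
  clocks here.
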