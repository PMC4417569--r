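#' @title Compact prefix trie construction
#' @name build_trie
#' @description
#' The trie indexes every read as a root-to-node path.  Unary chains are
#' collapsed: a node stores only the chain length (`chain_len`) and its
#' characters are recovered from the 2-bit text through the node's
#' representative read (the read with id equal to the interval lower bound).
#' Every node carries the interval `[r1, r2]` of lexicographic read ids that
#' share the path prefix, and `n_end`, the number of reads ending exactly at
#' the node.  On a prefix-free read set every terminal node is a leaf and
#' every internal node has at least two children; when one read is a prefix
#' of another (possible when containment filtering is off) the shorter read
#' terminates at an internal node and occupies the low end
#' `[r1, r1 + n_end - 1]` of its interval, with the children tiling the rest.
NULL

new_trie <- function(core, read_set, stage, permutation) {
  structure(
    list(
      node_count = core$node_count,
      label = ifelse(is.na(core$label_code), NA_character_,
                     BASES[core$label_code]),
      chain_len = core$chain_len,
      r1 = core$r1, r2 = core$r2, n_end = core$n_end,
      children = {
        ch <- core$children
        rownames(ch) <- BASES
        ch
      },
      enders = core$enders,
      comparisons = core$comparisons,
      stage = stage,
      permutation = permutation,
      read_set = read_set,
      k = read_set$k, n = read_set$n
    ),
    class = "cpt_trie"
  )
}

#' @export
print.cpt_trie <- function(x, ...) {
  cat(sprintf(
    "compact prefix trie: %d nodes over k = %d reads (n = %.0f bases)%s\n",
    x$node_count, x$k, x$n,
    if (x$stage == "stage1") " [stage 1: intervals not yet assigned]" else ""))
  invisible(x)
}

# positions (rows of read_set$reads) ordered by lexicographic id
pos_by_id <- function(trie) order(trie$permutation)

#' Build the trie from a sorted read set
#'
#' Inserts reads in id order; each insertion follows the path for the read
#' and either extends intervals (match), splits a node at the mismatch
#' position within its chain, or opens a fresh branch.  A read equal to an
#' already inserted read extends the terminal node's interval.
#'
#' @param rs a lexicographically sorted [read_set()] (see [sort_reads()]).
#' @return A `cpt_trie` with final intervals.
#' @export
#' @examples
#' rs <- sort_reads(read_set(c("AAGGG", "ACTTT", "AGGCT", "GCCAC", "TCCGC")))
#' tr <- build_sorted(rs)
#' tr$node_count
build_sorted <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  if (rs$k == 0L) stop("empty read set")
  if (is.unsorted(rs$reads$sequence))
    stop("reads are not in lexicographic order; use sort_reads() first")
  if (!rs$sorted) {
    rs$sorted <- TRUE
    rs$reads$id <- seq_len(rs$k)
    if (is.null(rs$permutation)) {
      perm <- integer(rs$k)
      perm[rs$reads$original_index] <- seq_len(rs$k)
      rs$permutation <- perm
    }
  }
  core <- cpp_build(rs$text, rs$offsets, rs$lengths,
                    seq_len(rs$k), sorted = TRUE)
  new_trie(core, rs, stage = "final", permutation = seq_len(rs$k))
}

#' Build the trie without sorting the reads
#'
#' Two stages: first the tree shape is built in file order with intervals
#' ignored (exact duplicates are pooled in per-node registries), then a
#' depth-first traversal ([relabel_intervals_dfs()]) assigns lexicographic
#' ids and intervals.  The result is structurally identical to
#' [build_sorted()] on the sorted read set.
#'
#' @param rs a [read_set()] in file order.
#' @return A `cpt_trie` with final intervals; its `permutation` maps each
#'   original index to the lexicographic id.
#' @export
build_unsorted <- function(rs) {
  relabel_intervals_dfs(build_stage1(rs))
}

#' Stage-1 trie: shape only, intervals unassigned
#'
#' @param rs a [read_set()]; insertion order is the row order.
#' @return A `cpt_trie` with `stage = "stage1"`.
#' @export
build_stage1 <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  if (rs$k == 0L) stop("empty read set")
  core <- cpp_build(rs$text, rs$offsets, rs$lengths,
                    seq_len(rs$k), sorted = FALSE)
  # provisional file-order tags on terminal nodes
  term <- which(core$n_end > 0L)
  for (v in term) core$r1[v] <- core$r2[v] <- core$enders[[v]][1L]
  new_trie(core, rs, stage = "stage1", permutation = NULL)
}

#' Depth-first interval relabeling (stage 2)
#'
#' Visits children in fixed A < C < G < T order; a counter assigns
#' consecutive ids, reads terminating at a node first (duplicates therefore
#' get consecutive ids, in registry order), then the subtrees.  Each node's
#' interval becomes the id range of its subtree.
#'
#' @param trie a stage-1 `cpt_trie`.
#' @return The finalized `cpt_trie`; `$permutation` equals the stable
#'   lexicographic-rank permutation of the original indices.
#' @export
relabel_intervals_dfs <- function(trie) {
  stopifnot(inherits(trie, "cpt_trie"))
  if (trie$stage != "stage1") stop("trie is already relabeled")
  rel <- cpp_relabel(trie$chain_len, trie$children, trie$enders, trie$k)
  out <- trie
  out$r1 <- rel$r1
  out$r2 <- rel$r2
  out$stage <- "final"
  out$permutation <- rel$permutation
  out
}

#' Duplicate-read registry
#'
#' @param trie a `cpt_trie`.
#' @return A list, one element per distinct sequence (terminal node), of the
#'   original indices of the reads carrying it, in insertion order.
#' @export
duplicate_registry <- function(trie) {
  term <- which(trie$n_end > 0L)
  out <- lapply(trie$enders[term],
                function(p) trie$read_set$reads$original_index[p])
  names(out) <- paste0("node", term)
  out
}

#' Resolve one implicit chain character
#'
#' Chain characters are not stored in the trie; the character compared at
#' `local_position` within a node is the character at text position
#' `path_len + local_position` of the node's representative read (the read
#' whose id is the interval lower bound).
#'
#' @param trie a finalized `cpt_trie`.
#' @param node node index.
#' @param local_position 1-based position within the node's chain
#'   (`<= chain_len + 1`).
#' @param path_len total characters on the path above the chain (edge labels
#'   plus fully traversed chains).
#' @return Single character, one of A/C/G/T.
#' @export
resolve_char <- function(trie, node, local_position, path_len) {
  stopifnot(inherits(trie, "cpt_trie"), trie$stage == "final")
  if (local_position > trie$chain_len[node] + 1L)
    stop("local_position beyond the node's chain")
  rep_id <- trie$r1[node]
  pos <- pos_by_id(trie)[rep_id]
  seq <- trie$read_set$reads$sequence[pos]
  at <- path_len + local_position
  if (at > nchar(seq))
    stop("internal inconsistency: position beyond the representative read")
  substr(seq, at, at)
}

#' Plain-text preorder dump of a trie
#'
#' One node per line: `depth<TAB>label<TAB>chain_len<TAB>r1<TAB>r2`, children
#' visited in A < C < G < T order.  The format is fixed so that structural
#' identity of two tries can be checked by comparing dumps.
#'
#' @param trie a `cpt_trie`.
#' @return Character vector of lines.
#' @export
trie_dump <- function(trie) {
  out <- character(trie$node_count)
  i <- 0L
  stack <- list(c(1L, 0L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- fr[1L]; d <- fr[2L]
    i <- i + 1L
    out[i] <- sprintf("%d\t%s\t%d\t%d\t%d", d,
                      if (is.na(trie$label[v])) "." else trie$label[v],
                      trie$chain_len[v], trie$r1[v], trie$r2[v])
    kids <- trie$children[, v]
    for (c in 4:1) if (kids[c] > 0L)
      stack[[length(stack) + 1L]] <- c(kids[c], d + 1L)
  }
  out[seq_len(i)]
}

#' Validate trie invariants
#'
#' Checks the structural invariants of the compact prefix trie: label and
#' child-slot consistency, the at-least-two-children rule for non-terminal
#' internal nodes, contiguous ordered interval tiling, terminal counts
#' against distinct sequences, and the 2k node bound.  With `deep = TRUE`
#' additionally reconstructs every terminal path string from the labels and
#' resolved chain characters and compares it to the actual read sequences.
#'
#' @param trie a finalized `cpt_trie`.
#' @param deep also check path soundness (costs O(n)).
#' @return Character vector of violations; empty when the trie is valid.
#' @export
validate_trie <- function(trie, deep = FALSE) {
  v <- character()
  say <- function(...) v[[length(v) + 1L]] <<- sprintf(...)
  N <- trie$node_count
  k <- trie$k
  if (trie$stage != "final") return("trie is stage-1: intervals unassigned")
  if (N > 2L * k) say("node_count %d exceeds 2k = %d", N, 2L * k)
  if (!is.na(trie$label[1L])) say("root has a label")
  if (trie$chain_len[1L] != 0L) say("root chain_len is not 0")
  if (trie$r1[1L] != 1L || trie$r2[1L] != k)
    say("root interval is not [1, k]")
  has_kids <- colSums(trie$children > 0L) > 0L
  nkids <- colSums(trie$children > 0L)
  for (nd in seq_len(N)) {
    kids <- trie$children[, nd]
    for (c in 1:4) if (kids[c] > 0L && trie$label[kids[c]] != BASES[c])
      say("node %d: child in slot %s has label %s", nd, BASES[c],
          trie$label[kids[c]])
    if (nd > 1L && is.na(trie$label[nd])) say("non-root node %d unlabeled", nd)
    if (trie$r1[nd] > trie$r2[nd])
      say("node %d: empty interval [%d,%d]", nd, trie$r1[nd], trie$r2[nd])
    if (nd > 1L && has_kids[nd] && trie$n_end[nd] == 0L && nkids[nd] < 2L)
      say("node %d: internal non-terminal node with a single child", nd)
    if (!has_kids[nd] && trie$n_end[nd] != trie$r2[nd] - trie$r1[nd] + 1L)
      say("node %d: leaf multiplicity %d != interval width", nd,
          trie$n_end[nd])
    # children tile [r1 + n_end, r2] in order, no gaps
    expect <- trie$r1[nd] + trie$n_end[nd]
    for (c in 1:4) {
      w <- kids[c]
      if (w > 0L) {
        if (trie$r1[w] != expect)
          say("node %d: child %d starts at %d, expected %d", nd, w,
              trie$r1[w], expect)
        expect <- trie$r2[w] + 1L
      }
    }
    if (has_kids[nd] && expect != trie$r2[nd] + 1L)
      say("node %d: children do not tile up to r2", nd)
  }
  n_term <- sum(trie$n_end > 0L)
  n_distinct <- length(unique(trie$read_set$reads$sequence))
  if (n_term != n_distinct)
    say("terminal node count %d != distinct sequences %d", n_term, n_distinct)
  if (sum(trie$n_end) != k)
    say("sum of n_end %d != k", sum(trie$n_end))
  if (deep) v <- c(v, .validate_paths(trie))
  v
}

# Path soundness: rebuild each node's path string from labels + resolved
# chain characters; reads ending at a node must equal the path string, and
# all reads in the interval must have it as a prefix.
.validate_paths <- function(trie) {
  v <- character()
  seq_by_id <- trie$read_set$reads$sequence[pos_by_id(trie)]
  walk <- function(nd, prefix, plen) {
    if (nd > 1L) {
      prefix <- paste0(prefix, trie$label[nd])
      plen <- plen + 1L
      if (trie$chain_len[nd] > 0L) {
        for (lp in seq_len(trie$chain_len[nd]))
          prefix <- paste0(prefix, resolve_char(trie, nd, lp, plen))
        plen <- plen + trie$chain_len[nd]
      }
      for (id in trie$r1[nd]:trie$r2[nd])
        if (substr(seq_by_id[id], 1L, plen) != prefix)
          v[[length(v) + 1L]] <<- sprintf(
            "node %d: read id %d does not share the path prefix", nd, id)
      if (trie$n_end[nd] > 0L)
        for (id in trie$r1[nd]:(trie$r1[nd] + trie$n_end[nd] - 1L))
          if (seq_by_id[id] != prefix)
            v[[length(v) + 1L]] <<- sprintf(
              "node %d: terminating read id %d != path string", nd, id)
    }
    for (c in 1:4) {
      w <- trie$children[c, nd]
      if (w > 0L) walk(w, prefix, plen)
    }
  }
  walk(1L, "", 0L)
  v
}

#' Partition reads by their first characters
#'
#' Groups reads by their first `depth` characters (4 or 16 groups).  Groups
#' are disjoint, so each group's subtree of the trie can be built
#' independently; a read shorter than `depth` is grouped by its full
#' (shorter) prefix under its first character.
#'
#' @param rs a [read_set()].
#' @param depth 1 or 2.
#' @return Named list mapping each prefix to the original indices of its
#'   reads (file order preserved); empty groups included for the canonical
#'   4 or 16 prefixes.
#' @export
partition_reads_by_prefix <- function(rs, depth = 1L) {
  stopifnot(inherits(rs, "read_set"), depth %in% c(1L, 2L))
  key <- substr(rs$reads$sequence, 1L, depth)
  canon <- if (depth == 1L) BASES else
    as.vector(t(outer(BASES, BASES, paste0)))
  lv <- sort(unique(c(canon, key)), method = "radix")
  split(rs$reads$original_index, factor(key, levels = lv))
}

#' Build the trie by independent first-character partitions
#'
#' Emulates parallel construction: reads are grouped by their first `depth`
#' characters, each group's subtree is built independently (groups touch
#' disjoint parts of the tree, so no coordination is needed), and a single
#' depth-first relabeling assigns global ids.  The result is structurally
#' identical to [build_unsorted()] on the full set.
#'
#' @inheritParams partition_reads_by_prefix
#' @return A finalized `cpt_trie`.
#' @export
build_partitioned <- function(rs, depth = 1L) {
  groups <- partition_reads_by_prefix(rs, depth)
  ord <- match(unlist(groups, use.names = FALSE), rs$reads$original_index)
  core <- cpp_build(rs$text, rs$offsets[ord], rs$lengths[ord],
                    ord, sorted = FALSE)
  term <- which(core$n_end > 0L)
  for (v in term) core$r1[v] <- core$r2[v] <- core$enders[[v]][1L]
  st1 <- new_trie(core, rs, stage = "stage1", permutation = NULL)
  relabel_intervals_dfs(st1)
}
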