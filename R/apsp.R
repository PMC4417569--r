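#' Match one suffix against the trie
#'
#' Walks a proper suffix of a read down the trie.  If the suffix is
#' exhausted (at a node boundary or inside a chain) it is a prefix of every
#' read in the current node's interval; a chain mismatch or an absent branch
#' means no read has the suffix as a prefix.
#'
#' @param trie a finalized `cpt_trie`.
#' @param sequence the query read sequence.
#' @param start_pos 1-based suffix start, `2 <= start_pos <= nchar(sequence)`.
#' @return Integer vector `c(r1, r2)` of matched read ids, or `NULL`.
#' @export
match_suffix <- function(trie, sequence, start_pos) {
  stopifnot(inherits(trie, "cpt_trie"), trie$stage == "final")
  len <- nchar(sequence)
  if (start_pos < 2L || start_pos > len)
    stop("start_pos must be in [2, read length]")
  p <- pos_by_id(trie)
  res <- cpp_match_suffix(trie$chain_len, trie$children, trie$r1, trie$r2,
                          trie$read_set$text, trie$read_set$offsets[p],
                          substr(sequence, start_pos, len))
  res
}

#' Enumerate all-pairs suffix-prefix overlaps
#'
#' For every query read, proper suffixes are walked down the trie longest
#' first (start position 2, 3, ...), skipping suffixes shorter than
#' `min_len`.  Every successful walk yields one overlap per read id in the
#' matched interval.  Because a whole read is never a proper suffix of
#' itself, a read equal to another read's prefix is containment, not an
#' overlap — see [filter_contained()].
#'
#' @param trie a finalized `cpt_trie`.
#' @param min_len minimum overlap length (default 30).
#' @param mode `"all_matches"` records every matching suffix per pair,
#'   `"longest_only"` keeps the first (longest) per ordered pair and exposes
#'   the k-by-k length matrix, `"none"` only counts.
#' @param include_self also report self pairs (target = query).
#' @param mask optional [filter_contained()] mask; removed reads are skipped
#'   both as queries and as targets.
#' @param queries optional integer vector of query read ids (default: all).
#' @param matrix_cap refuse to allocate the longest-only matrix when
#'   `k` exceeds this (the matrix is O(k^2)).
#' @return An `overlap_result`: records data.frame (`query_id`, `target_id`,
#'   `length`, `start_pos`, plus file-order `query_orig` / `target_orig`),
#'   total match `counts`, per-query character-comparison counts, and in
#'   longest-only mode the length `matrix` (0 = no overlap).
#' @export
#' @examples
#' rs <- sort_reads(read_set(c("AAGGG", "ACTTT", "AGGCT", "GCCAC", "TCCGC")))
#' tr <- build_sorted(rs)
#' find_overlaps(tr, min_len = 1, mode = "longest_only")$records
find_overlaps <- function(trie, min_len = 30L,
                          mode = c("all_matches", "longest_only", "none"),
                          include_self = FALSE, mask = NULL, queries = NULL,
                          matrix_cap = 20000L) {
  stopifnot(inherits(trie, "cpt_trie"))
  if (trie$stage != "final") stop("trie intervals are not assigned yet")
  mode <- match.arg(mode)
  if (min_len < 1L) stop("min_len must be >= 1")
  k <- trie$k
  if (mode == "longest_only" && k > matrix_cap)
    stop("longest_only needs a ", k, "x", k,
         " matrix; raise matrix_cap to allow this")
  p <- pos_by_id(trie)
  orig_by_id <- trie$read_set$reads$original_index[p]
  removed_by_id <- rep(FALSE, k)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "removed_mask"), mask$k == k)
    removed_by_id <- mask$bits[orig_by_id]
  }
  if (is.null(queries)) queries <- which(!removed_by_id)
  else queries <- queries[!removed_by_id[queries]]
  res <- cpp_find_overlaps(trie$chain_len, trie$children, trie$r1, trie$r2,
                           trie$read_set$text,
                           trie$read_set$offsets[p],
                           trie$read_set$lengths[p],
                           as.integer(queries), as.integer(min_len),
                           switch(mode, none = 0L, longest_only = 1L,
                                  all_matches = 2L),
                           include_self, removed_by_id)
  records <- data.frame(
    query_id = res$query_id, target_id = res$target_id,
    length = res$length, start_pos = res$start_pos,
    query_orig = orig_by_id[res$query_id],
    target_orig = orig_by_id[res$target_id],
    stringsAsFactors = FALSE
  )
  mat <- NULL
  if (mode == "longest_only") {
    mat <- matrix(0L, k, k)
    if (nrow(records))
      mat[cbind(records$query_id, records$target_id)] <- records$length
  }
  structure(
    list(mode = mode, records = records, matrix = mat, counts = res$counts,
         comparisons = setNames(res$comparisons, queries),
         min_len = min_len, include_self = include_self,
         k = k, n = trie$n),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: mode = %s, min_len = %d, k = %d, matches = %.0f\n",
    x$mode, x$min_len, x$k, x$counts))
  if (nrow(x$records)) print(head(x$records, 10L))
  invisible(x)
}

#' Longest-overlap matrix
#'
#' @param result an `overlap_result` produced in `longest_only` mode.
#' @return Integer k-by-k matrix; entry (i, t) is the longest suffix-prefix
#'   overlap of query i onto target t, 0 if none.
#' @export
overlap_matrix <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  if (is.null(result$matrix))
    stop("overlap matrix is only available in longest_only mode")
  result$matrix
}
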