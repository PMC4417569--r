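#' Containment prefiltering of reads
#'
#' In the assembly context a read that is a prefix or a suffix of another
#' read carries no extra overlap information and can be removed before
#' overlap finding.  Three cases are detected on the built trie:
#' prefix-contained reads terminate at a node that still has children;
#' duplicate reads share one terminal node (the copy with the smallest
#' original index survives); suffix-contained reads are found by walking
#' every proper suffix of every read — a suffix that is exhausted exactly at
#' a terminal node boundary equals the full string of the reads ending
#' there.
#'
#' @name prefix_filter
NULL

new_removed_mask <- function(k) {
  structure(list(bits = rep(FALSE, k), reason = rep(NA_character_, k), k = k),
            class = "removed_mask")
}

#' @export
print.removed_mask <- function(x, ...) {
  cat(sprintf("removed_mask: %d of %d reads removed\n", sum(x$bits), x$k))
  if (any(x$bits)) print(table(x$reason[x$bits]))
  invisible(x)
}

#' Mark prefix-contained and duplicate reads
#'
#' @param trie a finalized `cpt_trie`.
#' @param mask an existing mask to update, or `NULL` to start fresh.
#' @return A `removed_mask` (bits indexed by original read index) with
#'   reasons `prefix_contained` / `duplicate`.
#' @export
filter_prefix_contained <- function(trie, mask = NULL) {
  stopifnot(inherits(trie, "cpt_trie"), trie$stage == "final")
  if (is.null(mask)) mask <- new_removed_mask(trie$k)
  orig_of_pos <- trie$read_set$reads$original_index
  has_kids <- colSums(trie$children > 0L) > 0L
  for (v in which(trie$n_end > 0L)) {
    origs <- orig_of_pos[trie$enders[[v]]]
    if (has_kids[v]) {
      # the path continues: every read ending here prefixes a longer read
      hit <- origs[!mask$bits[origs]]
      mask$bits[hit] <- TRUE
      mask$reason[hit] <- "prefix_contained"
    } else if (length(origs) > 1L) {
      drop <- setdiff(origs, min(origs))
      drop <- drop[!mask$bits[drop]]
      mask$bits[drop] <- TRUE
      mask$reason[drop] <- "duplicate"
    }
  }
  mask
}

#' Mark suffix-contained reads
#'
#' Walks every proper suffix of every read down the trie (the same walks the
#' overlap enumeration performs); reads whose full sequence equals such a
#' suffix are marked.
#'
#' @param trie a finalized `cpt_trie`.
#' @param mask an existing mask to update, or `NULL` to start fresh.
#' @return The updated `removed_mask` (reason `suffix_contained`; an earlier
#'   reason wins).
#' @export
filter_suffix_contained <- function(trie, mask = NULL) {
  stopifnot(inherits(trie, "cpt_trie"), trie$stage == "final")
  if (is.null(mask)) mask <- new_removed_mask(trie$k)
  p <- pos_by_id(trie)
  hits <- cpp_suffix_containment(trie$chain_len, trie$children, trie$r1,
                                 trie$n_end, trie$read_set$text,
                                 trie$read_set$offsets[p],
                                 trie$read_set$lengths[p])
  orig_of_pos <- trie$read_set$reads$original_index
  for (v in which(hits)) {
    origs <- orig_of_pos[trie$enders[[v]]]
    hit <- origs[!mask$bits[origs]]
    mask$bits[hit] <- TRUE
    mask$reason[hit] <- "suffix_contained"
  }
  mask
}

#' Full containment filter
#'
#' Runs the prefix/duplicate pass, then the suffix pass ("first pass wins"
#' for the recorded reason).  The filter is a pure function of the trie and
#' is therefore idempotent.
#'
#' @param trie a finalized `cpt_trie`.
#' @return A `removed_mask`; read u is removed iff some other read v has u
#'   as a prefix or a suffix (for exact duplicates the copy with the
#'   smallest original index survives).
#' @export
#' @examples
#' rs <- read_set(c("ACGT", "AC", "GT"))
#' tr <- build_unsorted(rs)
#' filter_contained(tr)
filter_contained <- function(trie) {
  filter_suffix_contained(trie, filter_prefix_contained(trie))
}
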