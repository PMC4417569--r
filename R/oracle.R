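#' Brute-force all-pairs suffix-prefix reference
#'
#' Deliberately naive reference implementation used for differential
#' testing: every proper suffix of every read is compared, as a string,
#' against every read prefix of the same length via a join of two substring
#' tables.  Shares no code with the trie path.
#'
#' @param rs a [read_set()].
#' @param min_len minimum overlap length.
#' @param include_self report self pairs.
#' @param mode `"all"` for every matching (pair, length), `"longest"` for
#'   the per-pair maximum.
#' @return data.frame with columns `query_orig`, `target_orig`, `length`
#'   (and `start_pos` in `"all"` mode), sorted by (query, target,
#'   decreasing length).  Indices are original (file-order) read indices.
#' @export
#' @examples
#' rs <- read_set(c("AAGGG", "ACTTT", "AGGCT", "GCCAC", "TCCGC"))
#' brute_force_apsp(rs, min_len = 1, mode = "longest")
brute_force_apsp <- function(rs, min_len = 1L, include_self = FALSE,
                             mode = c("all", "longest")) {
  stopifnot(inherits(rs, "read_set"), min_len >= 1L)
  mode <- match.arg(mode)
  seqs <- rs$reads$sequence
  orig <- rs$reads$original_index
  lens <- rs$reads$length
  k <- rs$k
  empty <- data.frame(query_orig = integer(), target_orig = integer(),
                      length = integer(), start_pos = integer())
  # proper suffixes of length >= min_len
  ns <- pmax(lens - min_len, 0L)
  if (sum(ns) == 0L) return(if (mode == "all") empty else empty[1:0, 1:3])
  qrow <- rep.int(seq_len(k), ns)
  L <- sequence(ns) + (min_len - 1L)
  suf <- data.table::data.table(
    s = substring(seqs[qrow], lens[qrow] - L + 1L, lens[qrow]),
    L = L, query = orig[qrow], start_pos = lens[qrow] - L + 1L)
  # prefixes of length >= min_len (a whole read may be another's suffix)
  np <- pmax(lens - min_len + 1L, 0L)
  prow <- rep.int(seq_len(k), np)
  L2 <- sequence(np) + (min_len - 1L)
  pre <- data.table::data.table(
    s = substring(seqs[prow], 1L, L2), L = L2, target = orig[prow])
  hits <- merge(suf, pre, by = c("s", "L"), allow.cartesian = TRUE)
  if (!include_self) hits <- hits[hits$query != hits$target, ]
  out <- data.frame(query_orig = hits$query, target_orig = hits$target,
                    length = hits$L, start_pos = hits$start_pos)
  if (mode == "longest") {
    dt <- data.table::as.data.table(out)
    out <- as.data.frame(dt[, list(length = max(length)),
                            by = c("query_orig", "target_orig")])
  }
  out <- out[order(out$query_orig, out$target_orig, -out$length), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force containment reference
#'
#' Read u is marked removed iff some other read v has u as a prefix or a
#' suffix; for exact duplicates the copy with the smallest original index
#' survives (unless it is itself contained in a longer read).
#'
#' @param rs a [read_set()].
#' @return A `removed_mask` over original indices.
#' @export
brute_force_containment <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  ord <- order(rs$reads$original_index)
  seqs <- rs$reads$sequence[ord]
  lens <- rs$reads$length[ord]
  k <- rs$k
  mask <- new_removed_mask(k)
  first_of <- !duplicated(seqs)
  for (u in seq_len(k)) {
    longer <- lens > lens[u]
    if (any(longer & startsWith(seqs, seqs[u]))) {
      mask$bits[u] <- TRUE
      mask$reason[u] <- "prefix_contained"
    } else if (any(longer & endsWith(seqs, seqs[u]))) {
      mask$bits[u] <- TRUE
      mask$reason[u] <- "suffix_contained"
    } else if (!first_of[u]) {
      mask$bits[u] <- TRUE
      mask$reason[u] <- "duplicate"
    }
  }
  mask
}

#' Differential verification of the trie path against the oracle
#'
#' Builds the trie (unsorted construction), enumerates all matches, and
#' compares them with [brute_force_apsp()].
#'
#' @param rs a [read_set()].
#' @param min_len minimum overlap length.
#' @return Invisibly `TRUE` on agreement; otherwise a data.frame of the
#'   differing records (attribute of the error condition) is reported via
#'   `stop()`.
#' @export
verify_against_oracle <- function(rs, min_len = 30L) {
  trie <- build_unsorted(rs)
  got <- find_overlaps(trie, min_len = min_len, mode = "all_matches")
  a <- got$records[, c("query_orig", "target_orig", "length")]
  b <- brute_force_apsp(rs, min_len = min_len)[,
         c("query_orig", "target_orig", "length")]
  key <- function(d) sort(paste(d$query_orig, d$target_orig, d$length))
  ka <- key(a)
  kb <- key(b)
  if (!identical(ka, kb)) {
    diff <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("trie and oracle disagree; first differing record: ", diff[1])
  }
  invisible(TRUE)
}
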