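#' Create a read set
#'
#' Bundles a collection of DNA reads with the 2-bit encoded concatenation of
#' their sequences (A=00, C=01, G=10, T=11, four bases per byte).  All
#' downstream trie operations address characters through this encoded text,
#' so the in-memory footprint of the text is 2 bits per base.
#'
#' @param sequences character vector of reads over \{A,C,G,T\}
#'   (case-insensitive; stored uppercased).
#' @param headers optional character vector of read names; defaults to
#'   `read1..readK`.
#' @return An object of class `read_set`: a list with `reads` (a data.frame
#'   with columns `id`, `original_index`, `header`, `sequence`, `length`),
#'   counts `k` and `n`, the packed `text` with per-read `offsets` and
#'   `lengths`, a `sorted` flag and (after [sort_reads()]) the permutation
#'   from original index to lexicographic id.
#' @export
#' @examples
#' rs <- read_set(c("AAGGG", "ACTTT", "AGGCT", "GCCAC", "TCCGC"))
#' rs$k
#' rs$n
read_set <- function(sequences, headers = NULL) {
  if (length(sequences) == 0L) stop("empty read set")
  sequences <- toupper(as.character(sequences))
  bad <- !grepl("^[ACGT]+$", sequences)
  if (any(bad))
    stop("read(s) ", paste(which(bad), collapse = ", "),
         " are empty or contain non-ACGT characters")
  if (is.null(headers)) headers <- paste0("read", seq_along(sequences))
  stopifnot(length(headers) == length(sequences))
  enc <- cpp_encode_bases(sequences)
  k <- length(sequences)
  reads <- data.frame(
    id = rep(NA_integer_, k),
    original_index = seq_len(k),
    header = as.character(headers),
    sequence = sequences,
    length = nchar(sequences),
    stringsAsFactors = FALSE
  )
  structure(
    list(reads = reads, k = k, n = sum(reads$length),
         text = enc$raw, offsets = enc$offsets, lengths = enc$lengths,
         sorted = FALSE, permutation = NULL),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: k = %d reads, n = %.0f bases%s\n", x$k, x$n,
              if (x$sorted) " (sorted)" else ""))
  print(head(x$reads, 5L))
  if (x$k > 5L) cat("...\n")
  invisible(x)
}

#' Sort a read set lexicographically
#'
#' Stable lexicographic (radix) sort of the reads; ids 1..k are the ranks.
#' Reads with equal sequences keep their input order and therefore receive
#' consecutive ids.
#'
#' @param rs a [read_set()].
#' @return A sorted `read_set` with `id` filled in and `permutation` mapping
#'   each original index to its 1-based lexicographic rank.
#' @export
sort_reads <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  if (rs$k == 0L) stop("empty read set")
  ord <- order(rs$reads$sequence, method = "radix")
  out <- rs
  out$reads <- rs$reads[ord, , drop = FALSE]
  out$reads$id <- seq_len(rs$k)
  rownames(out$reads) <- NULL
  out$offsets <- rs$offsets[ord]
  out$lengths <- rs$lengths[ord]
  out$sorted <- TRUE
  perm <- integer(rs$k)
  perm[out$reads$original_index] <- seq_len(rs$k)
  out$permutation <- perm
  out
}

#' Decode the 2-bit encoded text back to sequences
#'
#' @param rs a [read_set()].
#' @return Character vector of sequences, in the read set's current order.
#' @export
decode_reads <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  cpp_decode_bases(rs$text, rs$offsets, rs$lengths)
}
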