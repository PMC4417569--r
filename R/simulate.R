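#' Generate random reads of fixed total length
#'
#' Emulates the random test inputs for the overlap finder: k strings with
#' random lengths summing exactly to n, bases i.i.d. uniform over
#' \{A,C,G,T\}.  Lengths are a uniform random composition of n into k
#' positive parts (k-1 distinct cut points drawn uniformly).
#'
#' @param n total number of bases (`n >= k`).
#' @param k number of reads.
#' @param seed RNG seed; a fixed seed reproduces the set exactly.
#' @return A [read_set()] of k reads with `sum(lengths) == n`.
#' @export
#' @examples
#' rs <- generate_random_reads(100, 10, seed = 1)
#' sum(rs$reads$length)  # 100
generate_random_reads <- function(n, k, seed = NULL) {
  if (k < 1L) stop("k must be >= 1")
  if (n < k) stop("n must be >= k (each read needs at least one base)")
  if (!is.null(seed)) set.seed(seed)
  lens <- if (k == 1L) n else diff(c(0L, sort(sample.int(n - 1L, k - 1L)), n))
  big <- paste(sample(BASES, n, replace = TRUE), collapse = "")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  read_set(substring(big, starts, ends))
}

#' Generate overlapping reads by shredding a random genome
#'
#' Samples k substrings of a uniform random genome at random offsets, so
#' that true suffix-prefix overlaps exist by construction.  The returned
#' truth table records, for every ordered read pair, the exact longest
#' suffix-prefix match length found by direct string comparison
#' ([brute_force_apsp()]); overlaps longer than the planted tiling can occur
#' by chance and are included.
#'
#' @param genome_len genome length in bases.
#' @param k number of reads.
#' @param read_len_range inclusive range of read lengths (each sampled
#'   uniformly; capped at `genome_len`).
#' @param seed RNG seed.
#' @return A list: `read_set`, `truth` (data.frame `query_orig`,
#'   `target_orig`, `length` of the longest overlap per ordered pair), and
#'   the `genome` string.
#' @export
generate_overlapping_reads <- function(genome_len, k,
                                       read_len_range = c(50L, 150L),
                                       seed = NULL) {
  if (k < 1L) stop("k must be >= 1")
  if (min(read_len_range) < 1L || max(read_len_range) > genome_len)
    stop("read lengths must lie in [1, genome_len]")
  if (!is.null(seed)) set.seed(seed)
  genome <- paste(sample(BASES, genome_len, replace = TRUE), collapse = "")
  lens <- sample(read_len_range[1]:read_len_range[2], k, replace = TRUE)
  starts <- vapply(lens, function(l) sample.int(genome_len - l + 1L, 1L),
                   integer(1))
  rs <- read_set(substring(genome, starts, starts + lens - 1L))
  truth <- if (k > 1L) {
    bf <- brute_force_apsp(rs, min_len = 1L, mode = "longest")
    bf[, c("query_orig", "target_orig", "length")]
  } else {
    data.frame(query_orig = integer(), target_orig = integer(),
               length = integer())
  }
  list(read_set = rs, truth = truth, genome = genome)
}
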