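#' Work estimation and load partitioning
#'
#' Overlap enumeration processes every proper suffix of a read, so a read of
#' length l costs about l(l+1)/2 character comparisons.  The partitioners
#' below turn that estimate into an assignment of reads (by lexicographic
#' id) to p workers; all are pure functions, so plans are identical across
#' runs and the overlap output is independent of the strategy.
#'
#' @name scheduling
NULL

#' Estimated work for one read
#'
#' @param x a [read_set()], a character vector of sequences, or a numeric
#'   vector of read lengths.
#' @return Numeric vector of work estimates `l * (l + 1) / 2` per read.
#' @export
#' @examples
#' estimate_work(c("ACC", "AATC"))  # 6 10
estimate_work <- function(x) {
  l <- if (inherits(x, "read_set")) x$reads$length
       else if (is.character(x)) nchar(x)
       else as.numeric(x)
  stopifnot(all(l >= 0))
  l * (l + 1) / 2
}

#' A worker's optimal share of the total work
#'
#' @param rs a [read_set()] (or anything [estimate_work()] accepts).
#' @param p number of workers.
#' @return Total estimated work divided by p.
#' @export
optimal_share <- function(rs, p) {
  if (p < 1L) stop("p must be >= 1")
  sum(estimate_work(rs)) / p
}

new_work_plan <- function(strategy, r, y, p, chunk_size = NA_integer_) {
  start_p <- vapply(seq_len(p), function(q) {
    w <- which(r == q)
    if (length(w)) min(w) else NA_integer_
  }, integer(1))
  structure(list(strategy = strategy, p = p, r = r, y = y,
                 start_p = start_p, chunk_size = chunk_size),
            class = "work_plan")
}

#' @export
print.work_plan <- function(x, ...) {
  cat(sprintf("work_plan (%s): %d reads over %d workers\n",
              x$strategy, length(x$r), x$p))
  cat("loads:", paste(signif(x$y, 6), collapse = " "), "\n")
  invisible(x)
}

#' Equal-count partitioning
#'
#' Contiguous blocks of reads, sizes differing by at most one.  Ignores read
#' lengths; `y` reports the per-worker read counts.
#'
#' @param k number of reads.
#' @param p number of workers.
#' @return A `work_plan`.
#' @export
partition_equal_count <- function(k, p) {
  stopifnot(k >= 0L, p >= 1L)
  sizes <- rep(k %/% p, p)
  extra <- k %% p
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  r <- rep(seq_len(p), sizes)
  new_work_plan("equal_count", r, as.numeric(sizes), p)
}

#' Share-threshold partitioning
#'
#' Reads are assigned in id order to the current worker until its
#' accumulated work reaches the optimal share, then assignment moves to the
#' next worker; the last worker takes any remainder.
#'
#' @param rs a [read_set()].
#' @param p number of workers.
#' @return A `work_plan` with contiguous blocks and `start_p` recording each
#'   worker's first read.
#' @export
#' @examples
#' rs <- read_set(c("ACC", "AATC", "CGTC", "TTA", "TGA", "CCAT"))
#' partition_by_share(rs, 3)$r  # 1 1 2 2 3 3
partition_by_share <- function(rs, p) {
  stopifnot(inherits(rs, "read_set"), p >= 1L)
  w <- estimate_work(rs)
  share <- sum(w) / p
  k <- rs$k
  r <- integer(k)
  y <- numeric(p)
  q <- 1L
  acc <- 0
  for (i in seq_len(k)) {
    r[i] <- q
    acc <- acc + w[i]
    y[q] <- acc
    if (acc >= share && q < p) {
      q <- q + 1L
      acc <- 0
    }
  }
  new_work_plan("share_prefix", r, y, p)
}

#' Greedy least-loaded assignment
#'
#' Reads are processed in id order; each is assigned to the worker with the
#' currently smallest load (ties broken by the lowest worker index), whose
#' load then grows by the read's work estimate.
#'
#' @param rs a [read_set()].
#' @param p number of workers.
#' @return A `work_plan`; `max(y) - min(y)` never exceeds the largest single
#'   work estimate.
#' @export
greedy_assign <- function(rs, p) {
  stopifnot(inherits(rs, "read_set"), p >= 1L)
  w <- estimate_work(rs)
  r <- integer(rs$k)
  y <- numeric(p)
  for (i in seq_len(rs$k)) {
    q <- which.min(y)
    r[i] <- q
    y[q] <- y[q] + w[i]
  }
  new_work_plan("greedy", r, y, p)
}

#' Chunked work dispenser
#'
#' Models the shared-pointer dynamic distribution: consecutive,
#' non-overlapping ranges of `chunk_size` reads are handed out until the
#' read set is exhausted.  The dispenser is a closure; in a concurrent
#' setting advancing the shared position must be atomic — the contract here
#' is that no read is issued twice and none is skipped.
#'
#' @param k number of reads.
#' @param chunk_size reads per chunk (default 1024).
#' @return A list with `next_chunk()` (returns `c(from, to)` or `NULL` when
#'   exhausted) and `reset()`.
#' @export
#' @examples
#' d <- dynamic_chunks(10, 3)
#' d$next_chunk()  # 1 3
dynamic_chunks <- function(k, chunk_size = 1024L) {
  stopifnot(k >= 0L, chunk_size >= 1L)
  k <- as.integer(k)
  chunk_size <- as.integer(chunk_size)
  pos <- 1L
  list(
    next_chunk = function() {
      if (pos > k) return(NULL)
      from <- pos
      to <- min(pos + chunk_size - 1L, k)
      pos <<- to + 1L
      c(from, to)
    },
    reset = function() pos <<- 1L
  )
}

#' Dynamic-chunk partitioning as a plan
#'
#' Serial, deterministic realisation of the dynamic strategy: chunks from
#' [dynamic_chunks()] are claimed by workers in round-robin order.
#'
#' @param rs a [read_set()].
#' @param p number of workers.
#' @param chunk_size reads per chunk.
#' @return A `work_plan`.
#' @export
partition_dynamic <- function(rs, p, chunk_size = 1024L) {
  stopifnot(inherits(rs, "read_set"), p >= 1L)
  w <- estimate_work(rs)
  d <- dynamic_chunks(rs$k, chunk_size)
  r <- integer(rs$k)
  y <- numeric(p)
  q <- 1L
  repeat {
    ch <- d$next_chunk()
    if (is.null(ch)) break
    idx <- ch[1]:ch[2]
    r[idx] <- q
    y[q] <- y[q] + sum(w[idx])
    q <- if (q == p) 1L else q + 1L
  }
  new_work_plan("dynamic_chunk", r, y, p, chunk_size)
}

#' Build a work plan by strategy name
#'
#' @param rs a [read_set()].
#' @param p number of workers.
#' @param strategy one of `equal`, `share`, `dynamic`, `greedy`.
#' @param chunk_size chunk size for the dynamic strategy.
#' @return A `work_plan`.
#' @export
work_plan <- function(rs, p, strategy = c("equal", "share", "dynamic",
                                          "greedy"), chunk_size = 1024L) {
  switch(match.arg(strategy),
         equal = partition_equal_count(rs$k, p),
         share = partition_by_share(rs, p),
         dynamic = partition_dynamic(rs, p, chunk_size),
         greedy = greedy_assign(rs, p))
}

#' Run overlap finding under a work plan
#'
#' Executes the per-worker query sets serially in worker order and
#' concatenates the results; the combined record set is identical to the
#' single-worker run for every strategy.
#'
#' @param trie a finalized `cpt_trie`.
#' @param plan a `work_plan` over the same k reads.
#' @param ... passed to [find_overlaps()].
#' @return An `overlap_result` with records sorted by
#'   (query_id, start_pos, target_id).
#' @export
run_plan <- function(trie, plan, ...) {
  stopifnot(inherits(plan, "work_plan"), length(plan$r) == trie$k)
  parts <- lapply(seq_len(plan$p), function(q) {
    ids <- which(plan$r == q)
    if (!length(ids)) return(NULL)
    find_overlaps(trie, queries = ids, ...)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  recs <- do.call(rbind, lapply(parts, `[[`, "records"))
  recs <- recs[order(recs$query_id, recs$start_pos, recs$target_id), ,
               drop = FALSE]
  rownames(recs) <- NULL
  out <- parts[[1]]
  out$records <- recs
  out$counts <- sum(vapply(parts, `[[`, numeric(1), "counts"))
  out$comparisons <- unlist(lapply(parts, `[[`, "comparisons"))
  if (!is.null(out$matrix)) {
    m <- matrix(0L, trie$k, trie$k)
    if (nrow(recs)) m[cbind(recs$query_id, recs$target_id)] <- recs$length
    out$matrix <- m
  }
  out
}
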