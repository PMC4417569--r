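test_that("sorted construction reproduces the narrated intermediate states", {
  # first read alone: one branch, interval [1,1], chain_len 4
  t1 <- build_sorted(sort_reads(read_set(fig_strings[1])))
  expect_equal(t1$node_count, 2L)
  a <- node_where(t1, function(tr) !is.na(tr$label))
  expect_identical(t1$label[a], "A")
  expect_equal(t1$chain_len[a], 4L)
  expect_equal(c(t1$r1[a], t1$r2[a]), c(1L, 1L))

  # second read splits the node: v1 (chain 0, [1,2]), v2 (chain 3, [1,1]),
  # v3 (chain 3, [2,2])
  t2 <- build_sorted(sort_reads(read_set(fig_strings[1:2])))
  v1 <- node_where(t2, function(tr) !is.na(tr$label) & tr$r1 == 1 & tr$r2 == 2)
  expect_equal(t2$chain_len[v1], 0L)
  v2 <- t2$children["A", v1]
  v3 <- t2$children["C", v1]
  expect_equal(t2$chain_len[v2], 3L)
  expect_equal(c(t2$r1[v2], t2$r2[v2]), c(1L, 1L))
  expect_equal(t2$chain_len[v3], 3L)
  expect_equal(c(t2$r1[v3], t2$r2[v3]), c(2L, 2L))

  # third read opens a fresh G branch: chain 3, [3,3]
  t3 <- build_sorted(sort_reads(read_set(fig_strings[1:3])))
  v1 <- node_where(t3, function(tr) !is.na(tr$label) & tr$r2 == 3 &
                     tr$r1 == 1)
  g <- t3$children["G", v1]
  expect_gt(g, 0L)
  expect_equal(t3$chain_len[g], 3L)
  expect_equal(c(t3$r1[g], t3$r2[g]), c(3L, 3L))

  # full tree: 5 leaves, A-child of root has interval [1,3] and chain 0
  t5 <- build_sorted(sort_reads(read_set(fig_strings)))
  expect_equal(sum(t5$n_end > 0), 5L)
  ra <- t5$children["A", 1]
  expect_equal(t5$chain_len[ra], 0L)
  expect_equal(c(t5$r1[ra], t5$r2[ra]), c(1L, 3L))
  expect_length(validate_trie(t5, deep = TRUE), 0L)
})

test_that("duplicate reads share one leaf with a widened interval", {
  tr <- build_sorted(sort_reads(read_set(c("AC", "AC"))))
  leaf <- node_where(tr, function(t) t$n_end > 0)
  expect_equal(c(tr$r1[leaf], tr$r2[leaf]), c(1L, 2L))
  expect_equal(tr$n_end[leaf], 2L)
  expect_length(validate_trie(tr), 0L)
})

test_that("build_sorted rejects unsorted input and empty sets", {
  expect_error(build_sorted(read_set(c("T", "A"))), "not in lexicographic")
  expect_error(build_unsorted(structure(list(k = 0L), class = "read_set")),
               "empty")
})

test_that("unsorted construction matches sorted construction node-for-node", {
  # reverse file order of the example strings
  tu <- build_unsorted(read_set(rev(fig_strings)))
  ts <- build_sorted(sort_reads(read_set(fig_strings)))
  expect_identical(trie_dump(tu), trie_dump(ts))
  # permutation: reversed input => reversed ranks
  expect_identical(tu$permutation, 5:1)

  # single read
  t1 <- build_unsorted(read_set("GGA"))
  expect_identical(t1$permutation, 1L)
  leaf <- node_where(t1, function(t) t$n_end > 0)
  expect_equal(c(t1$r1[leaf], t1$r2[leaf]), c(1L, 1L))

  # three copies of one read: consecutive ids, registry of 3
  t3 <- build_unsorted(read_set(c("CGT", "AAA", "CGT", "CGT")))
  reg <- duplicate_registry(t3)
  trip <- reg[[which(vapply(reg, length, 1L) == 3L)]]
  expect_identical(trip, c(1L, 3L, 4L))
  ids <- t3$permutation[trip]
  expect_identical(sort(ids), ids[1] + 0:2)
})

test_that("relabeling yields the stable lexicographic-rank permutation", {
  set.seed(5)
  for (i in 1:10) {
    rs <- rand_reads(sample(2:60, 1), c(2L, 25L))
    tu <- build_unsorted(rs)
    expect_identical(tu$permutation, sort_reads(rs)$permutation)
  }
})

test_that("structural equivalence and invariants hold on fuzzed read sets", {
  set.seed(123)
  for (i in 1:25) {
    rs <- if (i %% 2 == 0) rand_reads(sample(2:80, 1), c(3L, 40L))
          else generate_overlapping_reads(sample(300:1500, 1),
                                          sample(5:60, 1),
                                          c(20L, 60L))$read_set
    ts <- build_sorted(sort_reads(rs))
    tu <- build_unsorted(rs)
    expect_identical(trie_dump(tu), trie_dump(ts))
    expect_length(validate_trie(ts, deep = TRUE), 0L)
    d <- length(unique(rs$reads$sequence))
    expect_equal(sum(ts$n_end > 0), d)
    expect_lte(ts$node_count, 2L * rs$k)
    expect_lte(ts$comparisons, 2 * rs$n)
  }
})

test_that("resolve_char returns the implicit chain characters", {
  tr <- build_sorted(sort_reads(read_set(fig_strings)))
  g <- tr$children["G", 1]  # the G-leaf under the root
  # chain of the G-leaf stores CCAC; position 2 of GCCAC
  expect_identical(resolve_char(tr, g, 1L, 1L), "C")
  expect_identical(resolve_char(tr, g, 4L, 1L), "C")
  expect_error(resolve_char(tr, g, 6L, 1L), "chain")

  # every read in a node's interval agrees on every chain character
  set.seed(8)
  rs <- generate_overlapping_reads(800, 30, c(15L, 50L))$read_set
  t2 <- build_unsorted(rs)
  seq_by_id <- sort_reads(rs)$reads$sequence
  depth_info <- local({
    plen <- integer(t2$node_count)
    st <- list(c(1L, 0L))
    while (length(st)) {
      fr <- st[[length(st)]]
      st[[length(st)]] <- NULL
      v <- fr[1]
      plen[v] <- fr[2] + (v > 1L)
      for (c in 1:4) {
        w <- t2$children[c, v]
        if (w > 0) st[[length(st) + 1L]] <- c(w, plen[v] + t2$chain_len[v])
      }
    }
    plen
  })
  for (v in seq_len(t2$node_count)) {
    if (t2$chain_len[v] == 0L) next
    lp <- sample(t2$chain_len[v], 1L)
    ch <- resolve_char(t2, v, lp, depth_info[v])
    ids <- t2$r1[v]:t2$r2[v]
    expect_true(all(substr(seq_by_id[ids], depth_info[v] + lp,
                           depth_info[v] + lp) == ch))
  }
})

test_that("validate_trie reports an injected single-child internal node", {
  tr <- build_sorted(sort_reads(read_set(fig_strings)))
  expect_length(validate_trie(tr), 0L)
  bad <- tr
  # graft a fake unary internal node above the T-leaf
  tleaf <- node_where(tr, function(t) !is.na(t$label) & t$label == "T")
  n <- bad$node_count + 1L
  bad$node_count <- n
  bad$label <- c(bad$label, "T")
  bad$chain_len <- c(bad$chain_len, 0L)
  bad$r1 <- c(bad$r1, bad$r1[tleaf])
  bad$r2 <- c(bad$r2, bad$r2[tleaf])
  bad$n_end <- c(bad$n_end, 0L)
  bad$children <- cbind(bad$children, c(0L, 0L, 0L, 0L))
  bad$children["T", n] <- tleaf
  bad$children["T", 1] <- n
  bad$enders <- c(bad$enders, list(NULL))
  expect_match(validate_trie(bad), "single child", all = FALSE)
})

test_that("prefix-partitioned construction equals the single build", {
  rs <- read_set(fig_strings)
  gr <- partition_reads_by_prefix(rs, 1L)
  expect_identical(gr$A, 1:3)
  expect_identical(gr$G, 4L)
  expect_identical(gr$T, 5L)
  expect_length(gr$C, 0L)

  gr2 <- partition_reads_by_prefix(read_set(c("AAGT", "ACGT")), 2L)
  expect_identical(gr2$AA, 1L)
  expect_identical(gr2$AC, 2L)

  set.seed(31)
  for (i in 1:8) {
    rs <- rand_reads(sample(2:80, 1), c(1L, 40L))
    ref <- trie_dump(build_unsorted(rs))
    expect_identical(trie_dump(build_partitioned(rs, 1L)), ref)
    expect_identical(trie_dump(build_partitioned(rs, 2L)), ref)
  }
})
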