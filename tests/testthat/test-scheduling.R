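sched_rs <- read_set(sched_strings)

test_that("work estimates follow l(l+1)/2", {
  expect_equal(estimate_work(sched_strings), c(6, 10, 10, 6, 6, 10))
  expect_equal(estimate_work(0), 0)
  expect_equal(estimate_work(sched_rs), c(6, 10, 10, 6, 6, 10))
})

test_that("the optimal share divides total work by the worker count", {
  expect_equal(optimal_share(sched_rs, 3), 16)
  expect_equal(optimal_share(sched_rs, 1), 48)
  set.seed(4)
  rs <- rand_reads(40, c(5L, 50L))
  for (p in 1:5)
    expect_equal(p * optimal_share(rs, p), sum(estimate_work(rs)))
  expect_error(optimal_share(sched_rs, 0), "p")
})

test_that("equal-count partitioning makes near-equal contiguous blocks", {
  expect_identical(partition_equal_count(6, 3)$r, rep(1:3, each = 2))
  p73 <- partition_equal_count(7, 3)
  expect_identical(as.integer(table(p73$r)), c(3L, 2L, 2L))
  expect_false(is.unsorted(p73$r))
  # more workers than reads: singletons plus empty workers
  p58 <- partition_equal_count(5, 8)
  expect_identical(p58$r, 1:5)
  expect_identical(p58$start_p[6:8], rep(NA_integer_, 3))
})

test_that("share-threshold partitioning reproduces the worked assignment", {
  plan <- partition_by_share(sched_rs, 3)
  expect_identical(plan$r, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(plan$y, c(16, 16, 16))
  expect_identical(plan$start_p, c(1L, 3L, 5L))
  # equal-length reads reduce to near-equal counts
  rs_u <- read_set(rep("ACGTACGT", 9))
  expect_identical(partition_by_share(rs_u, 3)$r, rep(1:3, each = 3))
  # loads never exceed share by more than one read's work
  set.seed(21)
  for (i in 1:6) {
    rs <- rand_reads(sample(10:80, 1), c(5L, 100L))
    p <- sample(2:6, 1)
    plan <- partition_by_share(rs, p)
    w <- estimate_work(rs)
    expect_true(all(plan$y[-p] < optimal_share(rs, p) + max(w)))
    expect_equal(sum(plan$y), sum(w))
  }
})

test_that("greedy assignment tracks the least-loaded worker", {
  plan <- greedy_assign(sched_rs, 3)
  expect_equal(sort(plan$y), c(12, 16, 20))
  # hand simulation: 6->w1, 10->w2, 10->w3, 6->w1, 6->w2, 10->w3
  expect_identical(plan$r, c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_equal(plan$y, c(12, 16, 20))

  one <- greedy_assign(read_set("ACGT"), 3)
  expect_identical(one$r, 1L)

  set.seed(9)
  for (i in 1:6) {
    rs <- rand_reads(sample(10:100, 1), c(5L, 120L))
    p <- sample(2:8, 1)
    plan <- greedy_assign(rs, p)
    w <- estimate_work(rs)
    expect_lte(max(plan$y) - min(plan$y), max(w))
    expect_equal(sum(plan$y), sum(w))
  }
})

test_that("the chunk dispenser issues each read exactly once", {
  d <- dynamic_chunks(10, 3)
  expect_identical(d$next_chunk(), c(1L, 3L))
  expect_identical(d$next_chunk(), c(4L, 6L))
  expect_identical(d$next_chunk(), c(7L, 9L))
  expect_identical(d$next_chunk(), c(10L, 10L))
  expect_null(d$next_chunk())
  d$reset()
  expect_identical(d$next_chunk(), c(1L, 3L))

  expect_identical(dynamic_chunks(5, 10)$next_chunk(), c(1L, 5L))

  # simulated consumers drawing until empty cover 1..k disjointly
  set.seed(2)
  for (i in 1:5) {
    k <- sample(1:200, 1)
    d <- dynamic_chunks(k, sample(1:17, 1))
    seen <- integer()
    repeat {
      ch <- d$next_chunk()
      if (is.null(ch)) break
      expect_false(any(ch[1]:ch[2] %in% seen))
      seen <- c(seen, ch[1]:ch[2])
    }
    expect_identical(sort(seen), 1:k)
  }
})

test_that("every strategy assigns each read exactly once, deterministically", {
  set.seed(6)
  rs <- rand_reads(57, c(5L, 60L))
  for (s in c("equal", "share", "dynamic", "greedy")) {
    p1 <- work_plan(rs, 4, s, chunk_size = 8L)
    p2 <- work_plan(rs, 4, s, chunk_size = 8L)
    expect_identical(p1, p2)
    expect_length(p1$r, rs$k)
    expect_true(all(p1$r %in% 1:4))
    expect_identical(sort(unlist(lapply(1:4, function(q) which(p1$r == q)))),
                     seq_len(rs$k))
  }
})

test_that("overlap output is identical under every strategy and worker count", {
  set.seed(14)
  g <- generate_overlapping_reads(1200, 45, c(20L, 50L), seed = 14)
  tr <- build_unsorted(g$read_set)
  ref <- find_overlaps(tr, min_len = 5L)$records
  ref <- ref[order(ref$query_id, ref$start_pos, ref$target_id), ]
  for (s in c("equal", "share", "dynamic", "greedy"))
    for (p in c(1L, 3L, 7L)) {
      plan <- work_plan(g$read_set, p, s, chunk_size = 4L)
      got <- run_plan(tr, plan, min_len = 5L)$records
      expect_equal(got, ref, ignore_attr = TRUE)
    }
})
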