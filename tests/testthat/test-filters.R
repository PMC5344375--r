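test_that("length filter passes iff lengths differ by at most tau", {
  expect_true(length_filter(10, 10, 0))
  expect_true(length_filter(10, 12, 2))
  expect_false(length_filter(10, 13, 2))
  expect_equal(length_filter(c(5, 5, 5), c(5, 7, 9), 2), c(TRUE, TRUE, FALSE))
})

test_that("partition_segments produces the even tau+1 partition", {
  s <- partition_segments("abcdef", 1)
  expect_equal(s$segment, c("abc", "def"))
  expect_equal(s$start, c(0L, 3L))
  s2 <- partition_segments("abcdefg", 1)   # remainder goes to the tail
  expect_equal(s2$segment, c("abc", "defg"))
  s3 <- partition_segments("abcdefgh", 2)
  expect_equal(s3$segment, c("ab", "cde", "fgh"))
  s0 <- partition_segments("whole", 0)
  expect_equal(s0$segment, "whole")
  # strings shorter than tau+1 are classified too short, not an error
  expect_null(partition_segments("ab", 2))
})

test_that("segments reassemble the string for random inputs", {
  set.seed(11)
  for (i in 1:40) {
    tau <- sample(0:4, 1)
    l <- sample((tau + 1):30, 1)
    s <- random_string(l, letters[1:6])
    segs <- partition_segments(s, tau)
    expect_equal(nrow(segs), tau + 1L)
    expect_equal(paste0(segs$segment, collapse = ""), s)
    expect_equal(segs$start, cumsum(c(0L, head(segs$len, -1L))))
    # lengths differ by at most one, longer at the tail
    expect_true(all(diff(segs$len) >= 0))
    expect_lte(max(segs$len) - min(segs$len), 1L)
  }
})

test_that("an exact self-match lies inside every substring window", {
  set.seed(5)
  for (i in 1:30) {
    tau <- sample(0:3, 1)
    l <- sample((tau + 1):20, 1)
    s <- random_string(l, c("a", "b"))
    segs <- partition_segments(s, tau)
    for (j in seq_len(nrow(segs))) {
      w <- substring_window(segs$ordinal[j], segs$start[j], segs$len[j],
                            len_r = l, delta = 0L, tau = tau)
      expect_lte(w[1L], segs$start[j])
      expect_gte(w[2L], segs$start[j])
    }
  }
})

test_that("window completeness: every similar pair has a segment match in-window", {
  # exhaustive over all strings of length <= 6 on a binary alphabet
  all_s <- enumerate_strings(c("a", "b"), 6)
  d <- adist(all_s, all_s, costs = 1L)
  for (tau in 1:2) {
    hits <- which(upper.tri(d) & d <= tau, arr.ind = TRUE)
    for (row in seq_len(nrow(hits))) {
      s <- all_s[hits[row, 1L]]; r <- all_s[hits[row, 2L]]
      if (nchar(s) < tau + 1) next   # too-short strings bypass segmentation
      segs <- partition_segments(s, tau)
      delta <- nchar(r) - nchar(s)
      found <- FALSE
      for (j in seq_len(nrow(segs))) {
        if (segs$len[j] == 0L) next
        w <- substring_window(segs$ordinal[j], segs$start[j], segs$len[j],
                              nchar(r), delta, tau)
        if (w[1L] > w[2L]) next
        for (q in w[1L]:w[2L]) {
          if (substr(r, q + 1L, q + segs$len[j]) == segs$segment[j]) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      expect_true(found,
                  info = sprintf("pair (%s, %s) tau=%d lost by windows", s, r, tau))
    }
  }
})

test_that("windows widen monotonically with tau", {
  set.seed(9)
  for (i in 1:30) {
    p_i <- sample(0:10, 1); ord <- sample(1:3, 1)
    n <- sample(1:5, 1); len_r <- sample(10:25, 1); delta <- sample(-2:2, 1)
    prev <- NULL
    for (tau in ord:6) {
      w <- substring_window(ord, p_i, n, len_r, delta, tau)
      if (!is.null(prev) && prev[1L] <= prev[2L]) {
        expect_lte(w[1L], prev[1L])
        expect_gte(w[2L], prev[2L])
      }
      prev <- w
    }
  }
})

test_that("frequency_prune applies the 2*tau L1 bound", {
  expect_true(frequency_prune(c(3, 2, 5), c(3, 2, 6), 1))   # L1 = 1
  expect_false(frequency_prune(c(3, 2, 3), c(2, 3, 4), 1))  # L1 = 3 > 2
  expect_true(frequency_prune(c(1, 1), c(1, 1), 0))
  expect_error(frequency_prune(c(1, 2), c(1, 2, 3), 0), "different lengths")
})

test_that("one edit changes the joint-frequency L1 norm by at most 2", {
  fx <- table1_fixture()
  set.seed(21)
  for (i in 1:200) {
    s <- random_string(sample(1:25, 1), letters)
    k <- sample(0:4, 1)
    r <- apply_random_edits(s, k, letters, seed = i)
    l1 <- sum(abs(joint_frequency(s, fx$partition) -
                  joint_frequency(r, fx$partition)))
    expect_lte(l1, 2 * k)
  }
})

test_that("interval_block_distance lower-bounds member L1 distances", {
  fx <- table1_fixture()
  v0 <- interval_vector(c(3L, 2L, 5L), fx$scheme)
  expect_equal(interval_block_distance(v0, v0, fx$scheme), 0L)
  single <- as_interval_scheme(list(
    cbind(lo = c(1L, 3L, 4L, 5L), hi = c(2L, 3L, 4L, 6L))))
  expect_equal(interval_block_distance(1L, 4L, single), 3L)  # 5 - 2
  expect_equal(interval_block_distance(4L, 1L, single), 3L)
  expect_error(interval_block_distance(1L, 9L, single), "out of range")
  # property: bound <= L1 of any member pair, exhaustively on one split
  coll <- generate_collection(40, 4, 14, "acgt", seed = 13)
  blocks <- fq_split(coll, g = 2, bins = 3)
  scheme <- attr(blocks, "scheme")
  for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
    bound <- interval_block_distance(blocks[[i]]$key, blocks[[j]]$key, scheme)
    for (a in seq_along(blocks[[i]]$ids)) for (b in seq_along(blocks[[j]]$ids)) {
      l1 <- sum(abs(blocks[[i]]$fvec[a, ] - blocks[[j]]$fvec[b, ]))
      expect_lte(bound, l1)
    }
  }
})

test_that("no similar pair is dismissed by frequency or block-level pruning", {
  # filters are necessary conditions: check directly against the oracle
  coll <- generate_collection(80, 5, 18, "acgt", seed = 17)
  fx_blocks <- fq_split(coll, g = 3, bins = 4)
  scheme <- attr(fx_blocks, "scheme")
  part <- attr(fx_blocks, "partition")
  truth <- oracle_join(coll$text, 2)
  block_of <- integer(nrow(coll))
  for (bi in seq_along(fx_blocks)) block_of[fx_blocks[[bi]]$ids + 1L] <- bi
  for (row in seq_len(nrow(truth))) {
    a <- truth$id_a[row]; b <- truth$id_b[row]
    fa <- joint_frequency(coll$text[a + 1L], part)
    fb <- joint_frequency(coll$text[b + 1L], part)
    expect_true(frequency_prune(fa, fb, 2))
    expect_true(length_filter(nchar(coll$text[a + 1L]),
                              nchar(coll$text[b + 1L]), 2))
    bi <- block_of[a + 1L]; bj <- block_of[b + 1L]
    expect_lte(interval_block_distance(fx_blocks[[bi]]$key,
                                       fx_blocks[[bj]]$key, scheme), 2 * 2)
  }
})
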