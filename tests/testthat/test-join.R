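test_that("segment index holds tau+1 postings per indexed string", {
  idx <- build_segment_index("abcdef", 0L, tau = 1)
  expect_s3_class(idx, "segment_index")
  p1 <- idx$postings[["6|1|abc"]]
  p2 <- idx$postings[["6|2|def"]]
  expect_equal(p1[1, ], c(0L, 0L))
  expect_equal(p2[1, ], c(0L, 3L))
  # tau = 0: the whole string is the single segment
  idx0 <- build_segment_index(c("abc", "abc"), 0:1, tau = 0)
  expect_equal(nrow(idx0$postings[["3|1|abc"]]), 2L)
  # too-short strings are kept aside
  idx2 <- build_segment_index(c("ab", "abcdef"), 0:1, tau = 2)
  expect_equal(idx2$short_ids, 0L)
  expect_equal(idx2$n_indexed, 1L)
})

test_that("self_join finds exactly the oracle pairs within a block", {
  expect_pairs_equal(self_join(c("abc", "abd"), 1),
                     data.frame(id_a = 0L, id_b = 1L, edit_distance = 1L))
  expect_equal(nrow(self_join(c("abc", "xyz"), 1)), 0L)
  expect_equal(nrow(self_join("alone", 2)), 0L)
  set.seed(77)
  for (trial in 1:10) {
    texts <- vapply(1:40, function(i)
      random_string(sample(3:14, 1), c("a", "b", "c")), "")
    tau <- trial %% 3
    expect_pairs_equal(self_join(texts, tau), oracle_join(texts, tau))
  }
})

test_that("rs_join prunes block pairs beyond the interval bound without verifying", {
  coll <- string_collection(c("aaaa", "aaat", "tttt", "gttt"))
  part <- as_alphabet_partition(list("a", "t", "g"))
  scheme <- as_interval_scheme(list(
    cbind(lo = c(0L, 3L), hi = c(0L, 4L)),
    cbind(lo = c(0L, 3L), hi = c(1L, 4L)),
    cbind(lo = 0L, hi = 4L)))
  blocks <- fq_split(coll, part, scheme)
  expect_length(blocks, 2L)
  stats <- segjoin:::new_join_stats()
  res <- rs_join(blocks[[1]], blocks[[2]], tau = 1, scheme = scheme,
                 stats = stats)
  expect_equal(nrow(res), 0L)
  expect_equal(stats$verifications, 0L)   # pruned before any member work
  expect_equal(stats$blocks_pruned, 1L)
})

test_that("rs_join finds cross-block pairs", {
  b1 <- list(key = NULL, ids = 0L, texts = "acgtacgt")
  b2 <- list(key = NULL, ids = 1L, texts = "acgaacgt")  # one substitution
  res <- rs_join(b1, b2, tau = 1)
  expect_pairs_equal(res, data.frame(id_a = 0L, id_b = 1L, edit_distance = 1L))
  # cross-block completeness against the oracle
  coll <- generate_collection(60, 5, 16, "acgt", seed = 19)
  blocks <- fq_split(coll)
  scheme <- attr(blocks, "scheme")
  tau <- 2
  got <- list()
  for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
    if (i < j) got[[length(got) + 1L]] <-
      rs_join(blocks[[i]], blocks[[j]], tau, scheme)
    else if (i == j) got[[length(got) + 1L]] <- self_join(blocks[[i]], tau)
  }
  all_pairs <- do.call(rbind, lapply(got, as.data.frame))
  all_pairs <- all_pairs[order(all_pairs$id_a, all_pairs$id_b), ]
  expect_pairs_equal(all_pairs, oracle_join(coll$text, tau))
})

test_that("the schedule runs each block pair once and matches brute force", {
  coll <- generate_collection(120, 6, 22, "acgt", seed = 23)
  blocks <- fq_split(coll)
  tau <- 2
  res <- schedule_and_run(blocks, tau)
  st <- attr(res, "stats")
  nb <- length(blocks)
  expect_equal(st$rr_tasks, nb)
  expect_equal(st$rs_tasks, nb * (nb - 1) / 2)
  expect_pairs_equal(res, oracle_join(coll$text, tau))
})

test_that("worker count never changes the result", {
  coll <- generate_collection(80, 5, 18, letters, seed = 29)
  blocks <- fq_split(coll)
  r1 <- schedule_and_run(blocks, 2, workers = 1)
  r8 <- schedule_and_run(blocks, 2, workers = 8)
  expect_identical(as.data.frame(r1)[1:3], as.data.frame(r8)[1:3])
})

test_that("planted near-duplicates are recovered completely", {
  pp <- plant_pairs(100, 30, 2, 10, 25, "acgt", seed = 31)
  res <- schedule_and_run(fq_split(pp$collection), 2)
  key <- paste(res$id_a, res$id_b)
  for (row in seq_len(nrow(pp$truth))) {
    a <- min(pp$truth$id_a[row], pp$truth$id_b[row])
    b <- max(pp$truth$id_a[row], pp$truth$id_b[row])
    d <- oracle_ed(pp$collection$text[a + 1L], pp$collection$text[b + 1L])
    expect_lte(d, 2)                       # generator contract Ed <= k
    expect_true(paste(a, b) %in% key)      # engine recall
  }
})

test_that("disabling filters grows candidates but never changes the pairs", {
  coll <- generate_collection(60, 5, 15, "acgt", seed = 37)
  blocks <- fq_split(coll)
  tau <- 2
  configs <- list(
    join_control(use_length_filter = FALSE, use_freq_prune = FALSE,
                 use_extension = FALSE, use_block_prune = FALSE),
    join_control(use_freq_prune = FALSE, use_extension = FALSE,
                 use_block_prune = FALSE),
    join_control(use_extension = FALSE, use_block_prune = FALSE),
    join_control(use_block_prune = FALSE),
    join_control())
  base <- NULL
  prev_candidates <- Inf
  for (ctl in configs) {
    res <- schedule_and_run(blocks, tau, control = ctl)
    st <- attr(res, "stats")
    if (is.null(base)) base <- as.data.frame(res)[1:3]
    expect_identical(as.data.frame(res)[1:3], base)
    expect_lte(st$verifications, prev_candidates)
    prev_candidates <- st$verifications
  }
})

test_that("delta mode applies the per-pair threshold", {
  texts <- c("abcdefghij", "abcdefghix", "abcde")
  res <- similarity_join(texts, delta = 0.9)
  # only the length-10 pair is within floor(0.1 * 10) = 1
  expect_pairs_equal(res, data.frame(id_a = 0L, id_b = 1L, edit_distance = 1L))
  expect_error(similarity_join(texts, tau = 1, delta = 0.9), "exactly one")
  expect_error(similarity_join(texts), "exactly one")
})
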