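# Independent edit-distance oracle: base R's full-matrix Levenshtein DP.
oracle_ed <- function(s, r) as.integer(adist(s, r, costs = 1L))

# oracle pair set for a character vector (ids 0-based input order)
oracle_join <- function(texts, tau) {
  d <- adist(texts, texts, costs = 1L)
  hit <- which(upper.tri(d) & d <= tau, arr.ind = TRUE)
  df <- data.frame(id_a = hit[, 1L] - 1L, id_b = hit[, 2L] - 1L,
                   edit_distance = as.integer(d[hit]))
  df[order(df$id_a, df$id_b), , drop = FALSE]
}

expect_pairs_equal <- function(got, want_df) {
  got <- as.data.frame(got)[, c("id_a", "id_b", "edit_distance")]
  rownames(got) <- rownames(want_df) <- NULL
  expect_equal(got, want_df[, c("id_a", "id_b", "edit_distance")],
               ignore_attr = TRUE)
}

random_string <- function(len, alphabet) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

# all strings of length 1..maxlen over the given alphabet
enumerate_strings <- function(alphabet, maxlen) {
  out <- character(0)
  for (l in seq_len(maxlen)) {
    grid <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, apply(as.matrix(grid), 1L, paste0, collapse = ""))
  }
  out
}
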