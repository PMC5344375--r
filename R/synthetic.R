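#' Generate a seeded random string collection
#'
#' Uniform random strings: lengths uniform on `[len_min, len_max]`,
#' symbols uniform over `alphabet`. The same seed always yields the same
#' collection.
#'
#' @param n number of strings (>= 1).
#' @param len_min,len_max length range (1 <= len_min <= len_max).
#' @param alphabet character vector of symbols (or a single string whose
#'   characters form the alphabet).
#' @param seed integer RNG seed.
#' @return a [string_collection()] with ids `0..n-1`.
#' @export
generate_collection <- function(n, len_min, len_max, alphabet = letters,
                                seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (len_min < 1L || len_min > len_max) stop("need 1 <= len_min <= len_max")
  alphabet <- expand_alphabet(alphabet)
  withr_seed(seed, {
    lens <- len_min + sample.int(len_max - len_min + 1L, n, replace = TRUE) - 1L
    texts <- vapply(lens, function(l)
      paste0(sample(alphabet, l, replace = TRUE), collapse = ""), "")
  })
  string_collection(texts)
}

expand_alphabet <- function(alphabet) {
  alphabet <- as.character(alphabet)
  if (length(alphabet) == 0L) stop("alphabet must be non-empty")
  if (length(alphabet) == 1L && nchar(alphabet) > 1L)
    alphabet <- strsplit(alphabet, "", fixed = TRUE)[[1L]]
  unique(alphabet)
}

# run code under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}

#' Apply k random edit operations to a string
#'
#' Each operation is drawn uniformly from substitute / insert / delete with
#' a uniform position; a substitution resamples until the symbol actually
#' changes, and a deletion on an empty string is resampled as an
#' insertion. Edits may cancel, so `Ed(original, edited) <= k` (never
#' greater).
#'
#' @param text the string to edit.
#' @param k number of operations (>= 0).
#' @param alphabet symbols to draw from.
#' @param seed integer RNG seed.
#' @return the edited string.
#' @export
apply_random_edits <- function(text, k, alphabet = letters, seed = 1L) {
  if (k < 0L) stop("k must be >= 0")
  alphabet <- expand_alphabet(alphabet)
  withr_seed(seed, {
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    for (e in seq_len(k)) {
      op <- sample(c("sub", "ins", "del"), 1L)
      if (op == "del" && length(chars) == 0L) op <- "ins"
      if (op == "sub" && length(chars) == 0L) op <- "ins"
      if (op == "sub") {
        pos <- sample.int(length(chars), 1L)
        repl <- sample(alphabet, 1L)
        while (repl == chars[pos] && length(alphabet) > 1L)
          repl <- sample(alphabet, 1L)
        chars[pos] <- repl
      } else if (op == "ins") {
        pos <- sample.int(length(chars) + 1L, 1L)  # insert before pos
        chars <- append(chars, sample(alphabet, 1L), after = pos - 1L)
      } else {
        pos <- sample.int(length(chars), 1L)
        chars <- chars[-pos]
      }
    }
    paste0(chars, collapse = "")
  })
}

#' Brute-force similarity join (reference oracle)
#'
#' Computes the full-matrix Levenshtein distance for every unordered pair
#' (via [utils::adist()], independent of this package's banded verifier)
#' and keeps pairs with distance at most `tau`. Ground truth for all
#' completeness and equivalence tests; guarded against collections too
#' large for quadratic work.
#'
#' @param collection a [string_collection()] or character vector.
#' @param tau edit-distance threshold.
#' @param guard refuse collections larger than this (default 2000).
#' @return `similar_pairs`.
#' @export
brute_force_join <- function(collection, tau, guard = 2000L) {
  texts <- collection_texts(collection)
  ids <- collection_ids(collection)
  n <- length(texts)
  if (n > guard)
    stop(sprintf("collection size %d exceeds the quadratic-work guard (%d); sample it down",
                 n, guard))
  if (n < 2L) return(similar_pairs())
  d <- adist(texts, texts, costs = 1L)
  hit <- which(upper.tri(d) & d <= tau, arr.ind = TRUE)
  similar_pairs(ids[hit[, 1L]], ids[hit[, 2L]], d[hit])
}

#' Plant near-duplicate pairs in a random collection
#'
#' Generates a base collection and, for a subset of strings, appends a
#' mate obtained by at most `k` random edits, recording the planted pair
#' ids. Recorded script length `k` guarantees `Ed <= k` for each planted
#' pair (edits may cancel).
#'
#' @param n_base number of base strings.
#' @param n_planted number of planted mates.
#' @param k edits per mate.
#' @param len_min,len_max,alphabet,seed as in [generate_collection()].
#' @return list with `collection` (base + mates) and `truth` (data frame
#'   `id_a`, `id_b`, `k`).
#' @export
plant_pairs <- function(n_base, n_planted, k, len_min, len_max,
                        alphabet = letters, seed = 1L) {
  stopifnot(n_planted <= n_base)
  base <- generate_collection(n_base, len_min, len_max, alphabet, seed = seed)
  withr_seed(seed + 1000003L, {
    pick <- sample.int(n_base, n_planted)
    mate_seeds <- sample.int(.Machine$integer.max, n_planted)
  })
  mates <- vapply(seq_len(n_planted), function(j)
    apply_random_edits(base$text[pick[j]], k, alphabet, seed = mate_seeds[j]),
    "")
  mates[!nzchar(mates)] <- substr(base$text[pick[!nzchar(mates)]], 1L, 1L)
  coll <- string_collection(c(base$text, mates))
  truth <- data.frame(id_a = pick - 1L,
                      id_b = n_base + seq_len(n_planted) - 1L,
                      k = k)
  list(collection = coll, truth = truth)
}

#' Worked-example fixture: twelve strings with printed groups and intervals
#'
#' A small reference collection of twelve strings together with the
#' three-way alphabet grouping and the per-group count-interval scheme
#' used throughout the documentation's worked example. The scheme covers
#' every member string, and known signature values for the first four
#' strings are frozen in the test suite.
#'
#' @return list with `collection` (ids 0..11 for s1..s12), `partition`
#'   (3 groups) and `scheme` (4/3/5 intervals).
#' @export
table1_fixture <- function() {
  texts <- c("myfeltypre", "cusendusers", "jeffreyp", "lfredkobs",
             "nguisanint", "dreacutethay", "rewhoward", "ewpalaythe",
             "toniawbluher", "oldmillerthe", "ensgroupwar", "araliskovargu")
  partition <- as_alphabet_partition(list(
    c("g", "e", "b", "n", "j", "h", "w", "t", "x"),
    c("f", "a", "o", "m", "k", "i", "u", "q", "z"),
    c("d", "c", "l", "v", "s", "r", "p", "y")
  ))
  scheme <- as_interval_scheme(list(
    cbind(lo = c(1L, 3L, 4L, 5L), hi = c(2L, 3L, 4L, 6L)),
    cbind(lo = c(2L, 3L, 4L), hi = c(2L, 3L, 7L)),
    cbind(lo = c(1L, 2L, 3L, 4L, 5L), hi = c(1L, 2L, 3L, 4L, 6L))
  ))
  list(collection = string_collection(texts),
       partition = partition,
       scheme = scheme)
}
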