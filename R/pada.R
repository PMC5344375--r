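#' Collection-wide token counting
#'
#' Totals the occurrences of every symbol across the collection (the first
#' stage of the staged dataflow engine); the counts feed the same zigzag
#' collapsing as the blocked engine to form alphabet groups dynamically.
#'
#' @param collection a [string_collection()] or character vector.
#' @return named integer vector of total symbol counts, sorted by symbol.
#' @export
token_count <- function(collection) {
  texts <- collection_texts(collection)
  if (length(texts) == 0L) stop("empty collection")
  tab <- table(unlist(strsplit(texts, "", fixed = TRUE), use.names = FALSE))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

#' Group strings by exact joint-frequency vector
#'
#' The dataflow engine keys strings by their exact joint-frequency vector
#' (not interval vector): each keyed group holds the ids of all strings
#' sharing one vector.
#'
#' @param collection a [string_collection()] or character vector.
#' @param partition an `alphabet_partition`.
#' @return list of groups, each `list(key = <fvec>, ids = <ids>)`, ordered
#'   by key for determinism.
#' @export
keyed_groups <- function(collection, partition) {
  texts <- collection_texts(collection)
  ids <- collection_ids(collection)
  fmat <- joint_frequency_matrix(texts, partition)
  keys <- apply(fmat, 1L, paste, collapse = ",")
  uk <- sort(unique(keys))
  lapply(uk, function(kk) {
    idx <- which(keys == kk)
    list(key = fmat[idx[1L], ], ids = ids[idx], texts = texts[idx])
  })
}

#' Candidate group pairs under the L1 frequency bound
#'
#' Emits each unordered pair of keyed groups (including a group with
#' itself) whose keys are within L1 distance `2 * tau`; pairs beyond the
#' bound cannot contain similar strings. The double loop runs over
#' `j >= i` so each pair is emitted exactly once at the source.
#'
#' @param groups output of [keyed_groups()].
#' @param tau edit-distance threshold.
#' @return list of `c(i, j)` index pairs (1-based, `i <= j`).
#' @export
candidate_groups <- function(groups, tau) {
  out <- list()
  ng <- length(groups)
  for (i in seq_len(ng)) {
    for (j in i:ng) {
      if (sum(abs(groups[[i]]$key - groups[[j]]$key)) <= 2 * tau)
        out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

#' Run the staged dataflow join
#'
#' Single-node, deterministic implementation of the distributed join's
#' logical dataflow as pure staged transforms: (1) token counting and
#' zigzag alphabet collapsing; (2) map each string to its joint-frequency
#' vector and group ids by exact vector; (3) candidate generation over the
#' group-key pairs within L1 distance `2 * tau` (the broadcast join,
#' modeled as a read-only shared copy of the group list); (4) expand
#' candidate groups to id pairs, rejoin ids to texts, and verify each pair
#' with the banded verifier. Output is the canonical pair set, identical
#' to the blocked engine and to brute force on the same input.
#'
#' In a cluster port, stage (1) is a flatMap/reduceByKey over tokens,
#' stage (2) a map + groupByKey, stage (3) a mapPartitions over a
#' broadcast copy of the keyed groups, and stage (4) two joins against the
#' id-to-string table followed by a filter.
#'
#' @param collection a [string_collection()] or character vector.
#' @param tau edit-distance threshold (>= 0).
#' @param g number of alphabet groups.
#' @param partition optional `alphabet_partition` override (default:
#'   zigzag collapse of the collection's token counts).
#' @param control a [join_control()] (length filter and extension toggles
#'   apply to the verification stage).
#' @return `similar_pairs` with a `stats` attribute.
#' @export
run_padaflow <- function(collection, tau, g = 3L, partition = NULL,
                         control = join_control()) {
  texts <- collection_texts(collection)
  ids <- collection_ids(collection)
  tau <- as.integer(tau)
  if (tau < 0L) stop("tau must be >= 0")
  if (is.null(partition)) {
    counts <- token_count(texts)
    partition <- z_collapse(counts, g = min(g, length(counts)))
  }
  groups <- keyed_groups(collection, partition)
  cand <- candidate_groups(groups, tau)
  stats <- new_join_stats()
  codes <- lapply(texts, as_codepoints)
  names(codes) <- as.character(ids)
  lens <- nchar(texts); names(lens) <- as.character(ids)
  out <- new_pair_accumulator()
  for (cg in cand) {
    gi <- groups[[cg[1L]]]; gj <- groups[[cg[2L]]]
    if (cg[1L] == cg[2L]) {
      idsg <- gi$ids
      ni <- length(idsg)
      if (ni < 2L) next
      for (a in seq_len(ni - 1L)) for (b in (a + 1L):ni) {
        verify_pair_flow(idsg[a], idsg[b], codes, lens, tau, control, stats, out)
      }
    } else {
      for (a in gi$ids) for (b in gj$ids) {
        verify_pair_flow(a, b, codes, lens, tau, control, stats, out)
      }
    }
  }
  res <- acc_pairs(out)
  attr(res, "stats") <- stats_as_list(stats)
  res
}

verify_pair_flow <- function(a, b, codes, lens, tau, control, stats, out) {
  stats$candidates <- stats$candidates + 1L
  if (control$use_length_filter &&
      abs(lens[[as.character(a)]] - lens[[as.character(b)]]) > tau) {
    stats$pruned_length <- stats$pruned_length + 1L
    return(invisible(NULL))
  }
  stats$verifications <- stats$verifications + 1L
  res <- edit_distance_banded(codes[[as.character(a)]],
                              codes[[as.character(b)]], tau)
  if (!res$exceeds) {
    stats$pairs <- stats$pairs + 1L
    out$add(a, b, res$distance)
  }
  invisible(NULL)
}
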