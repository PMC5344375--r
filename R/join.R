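#' Control settings for the join pipeline
#'
#' Each filter can be toggled (all on by default) to instrument the
#' candidate flow; disabling filters never changes the output pair set,
#' only the amount of verification work.
#'
#' @param use_length_filter apply the length filter.
#' @param use_freq_prune apply the L1 joint-frequency filter.
#' @param use_extension apply extension-based pre-rejection before full
#'   banded verification.
#' @param use_block_prune apply interval-block-distance pruning in
#'   cross-block joins.
#' @return a `join_control` list.
#' @export
join_control <- function(use_length_filter = TRUE, use_freq_prune = TRUE,
                         use_extension = TRUE, use_block_prune = TRUE) {
  structure(list(use_length_filter = use_length_filter,
                 use_freq_prune = use_freq_prune,
                 use_extension = use_extension,
                 use_block_prune = use_block_prune),
            class = "join_control")
}

new_join_stats <- function() {
  env <- new.env(parent = emptyenv())
  env$candidates <- 0L        # (probe, candidate) hits surviving windows
  env$pruned_length <- 0L
  env$pruned_freq <- 0L
  env$pruned_extension <- 0L
  env$verifications <- 0L     # full banded verifications
  env$pairs <- 0L
  env$blocks_pruned <- 0L     # block pairs skipped by interval distance
  env$rr_tasks <- 0L
  env$rs_tasks <- 0L
  env
}

stats_as_list <- function(env) {
  as.list(env)[c("candidates", "pruned_length", "pruned_freq",
                 "pruned_extension", "verifications", "pairs",
                 "blocks_pruned", "rr_tasks", "rs_tasks")]
}

# Segment inverted index over one set of strings: key (length l, segment
# ordinal i, segment text) -> postings (position in `ids`, start p_i).
# Strings shorter than tau+1 cannot be segmented and are kept aside for
# exhaustive verification against length-compatible candidates.
#' Build a segment inverted index for a set of strings
#'
#' Splits every string of length >= tau+1 into its tau+1 pigeonhole
#' segments and indexes each under the key (string length, segment
#' ordinal, segment text). Too-short strings are listed separately.
#'
#' @param texts character vector of strings to index.
#' @param ids integer ids parallel to `texts`.
#' @param tau edit-distance threshold.
#' @return a `segment_index` list with the postings environment, the
#'   indexed lengths, and the too-short members.
#' @export
build_segment_index <- function(texts, ids, tau) {
  stopifnot(length(texts) == length(ids))
  env <- new.env(parent = emptyenv(), size = max(16L, 4L * length(texts)))
  lengths <- nchar(texts)
  short <- lengths < tau + 1L
  for (j in which(!short)) {
    segs <- partition_segments(texts[j], tau)
    keys <- paste0(lengths[j], "|", segs$ordinal, "|", segs$segment)
    for (a in seq_along(keys)) {
      key <- keys[a]
      post <- env[[key]]
      entry <- c(ids[j], segs$start[a])
      env[[key]] <- if (is.null(post)) matrix(entry, ncol = 2L)
                    else rbind(post, entry)
    }
  }
  structure(list(postings = env,
                 indexed_lengths = sort(unique(lengths[!short])),
                 short_ids = ids[short],
                 short_texts = texts[short],
                 tau = as.integer(tau),
                 n_indexed = sum(!short)),
            class = "segment_index")
}

#' @export
print.segment_index <- function(x, ...) {
  cat(sprintf("<segment_index: %d string(s) indexed, %d too short, tau = %d>\n",
              x$n_indexed, length(x$short_ids), x$tau))
  invisible(x)
}

# Probe one string against a segment index. For every indexed length l in
# [len_r - tau, len_r + tau] and every segment ordinal i, enumerate the
# multi-match-aware window of starts in the probe, look up the substring,
# and process each posting: length filter is implicit (l range), then
# frequency prune, extension pre-reject at this hit, and final banded
# verification (once per candidate pair, first verified hit wins).
# `accept` is a function(candidate_id) -> logical gating which postings
# may pair with this probe (used for self-join ordering).
probe_index <- function(index, r_text, r_id, r_codes, r_fvec,
                        fvec_by_id, codes_by_id, tau, control, stats,
                        accept = NULL, out) {
  len_r <- length(r_codes)
  decided <- new.env(parent = emptyenv())
  for (l in index$indexed_lengths) {
    if (control$use_length_filter && abs(l - len_r) > tau) next
    lay <- segment_layout(l, tau)
    delta <- len_r - l
    for (i in seq_len(tau + 1L)) {
      p_i <- lay[i, "start"]; n <- lay[i, "len"]
      if (n == 0L) next
      w <- substring_window(i, p_i, n, len_r, delta, tau)
      if (w[1L] > w[2L]) next
      for (q in w[1L]:w[2L]) {
        if (q + n > len_r) next
        sub <- intToUtf8(r_codes[(q + 1L):(q + n)])
        post <- index$postings[[paste0(l, "|", i, "|", sub)]]
        if (is.null(post)) next
        for (row in seq_len(nrow(post))) {
          cid <- post[row, 1L]
          if (!is.null(accept) && !accept(cid)) next
          ckey <- as.character(cid)
          if (!is.null(decided[[ckey]])) next
          stats$candidates <- stats$candidates + 1L
          if (control$use_freq_prune &&
              !frequency_prune(fvec_by_id[[ckey]], r_fvec, tau)) {
            stats$pruned_freq <- stats$pruned_freq + 1L
            decided[[ckey]] <- TRUE   # sound: frequency prune is hit-independent
            next
          }
          if (control$use_extension) {
            ext <- extension_verify(codes_by_id[[ckey]], r_codes,
                                    i, p_i, n, q, tau)
            if (ext$exceeds) {
              stats$pruned_extension <- stats$pruned_extension + 1L
              next  # this hit only; the pair may succeed at another hit
            }
          }
          stats$verifications <- stats$verifications + 1L
          res <- edit_distance_banded(codes_by_id[[ckey]], r_codes, tau)
          decided[[ckey]] <- TRUE
          if (!res$exceeds) {
            stats$pairs <- stats$pairs + 1L
            out$add(cid, r_id, res$distance)
          }
        }
      }
    }
  }
  invisible(NULL)
}

# growable pair accumulator
new_pair_accumulator <- function() {
  env <- new.env(parent = emptyenv())
  env$a <- integer(0); env$b <- integer(0); env$d <- integer(0)
  env$add <- function(id1, id2, dist) {
    env$a[[length(env$a) + 1L]] <- id1
    env$b[[length(env$b) + 1L]] <- id2
    env$d[[length(env$d) + 1L]] <- dist
  }
  env
}

acc_pairs <- function(env) similar_pairs(env$a, env$b, env$d)

# verify a probe exhaustively against explicit candidates (used for
# too-short strings that cannot be segmented)
verify_against <- function(r_codes, r_id, cand_ids, codes_by_id, tau,
                           control, stats, out) {
  len_r <- length(r_codes)
  for (cid in cand_ids) {
    ccodes <- codes_by_id[[as.character(cid)]]
    if (control$use_length_filter && abs(length(ccodes) - len_r) > tau) {
      stats$pruned_length <- stats$pruned_length + 1L
      next
    }
    stats$verifications <- stats$verifications + 1L
    res <- edit_distance_banded(ccodes, r_codes, tau)
    if (!res$exceeds) {
      stats$pairs <- stats$pairs + 1L
      out$add(cid, r_id, res$distance)
    }
  }
}

# shared worker over (index side texts/ids, probe side texts/ids)
join_sides <- function(idx_texts, idx_ids, probe_texts, probe_ids,
                       fvec_by_id, codes_by_id, tau, control, stats,
                       self = FALSE, out) {
  index <- build_segment_index(idx_texts, idx_ids, tau)
  seen_rank <- NULL
  if (self) {
    # probe order = index order; a probe may only pair with strings
    # indexed strictly before it, so each unordered pair arises once
    rank <- seq_along(idx_ids); names(rank) <- as.character(idx_ids)
    seen_rank <- rank
  }
  for (j in seq_along(probe_texts)) {
    r_id <- probe_ids[j]
    r_codes <- codes_by_id[[as.character(r_id)]]
    r_fvec <- fvec_by_id[[as.character(r_id)]]
    accept <- NULL
    if (self) {
      jr <- seen_rank[[as.character(r_id)]]
      accept <- function(cid) seen_rank[[as.character(cid)]] < jr
    }
    probe_index(index, probe_texts[j], r_id, r_codes, r_fvec,
                fvec_by_id, codes_by_id, tau, control, stats,
                accept = accept, out = out)
    # too-short indexed strings: exhaustive check against this probe
    if (length(index$short_ids) > 0L) {
      cand <- index$short_ids
      if (self) cand <- cand[vapply(cand, function(cid)
        seen_rank[[as.character(cid)]] < seen_rank[[as.character(r_id)]], NA)]
      verify_against(r_codes, r_id, cand, codes_by_id, tau, control, stats, out)
    }
  }
  invisible(NULL)
}

block_cache <- function(block) {
  codes <- lapply(block$texts, as_codepoints)
  names(codes) <- as.character(block$ids)
  fv <- lapply(seq_along(block$ids), function(j) block$fvec[j, ])
  names(fv) <- as.character(block$ids)
  list(codes = codes, fvec = fv)
}

#' All similar pairs within one partition block (self-join)
#'
#' Sorts the block members by decreasing length (ties by id), indexes them
#' incrementally and probes each member against the already-indexed
#' prefix, so every unordered pair is considered exactly once. Candidate
#' flow: length filter (via indexed-length range), segment/window probe,
#' L1 frequency prune, extension pre-reject, banded verification.
#'
#' @param block a block from [fq_split()] (list with `ids`, `texts`,
#'   `fvec`), or a character vector of strings.
#' @param tau edit-distance threshold.
#' @param control a [join_control()].
#' @param stats optional stats environment (internal instrumentation).
#' @return a `similar_pairs` data frame.
#' @export
self_join <- function(block, tau, control = join_control(), stats = NULL) {
  block <- as_block(block)
  if (is.null(stats)) stats <- new_join_stats()
  stats$rr_tasks <- stats$rr_tasks + 1L
  out <- new_pair_accumulator()
  if (length(block$ids) >= 2L) {
    ord <- order(-nchar(block$texts), block$ids)
    cache <- block_cache(block)
    join_sides(block$texts[ord], block$ids[ord],
               block$texts[ord], block$ids[ord],
               cache$fvec, cache$codes, as.integer(tau), control, stats,
               self = TRUE, out = out)
  }
  res <- acc_pairs(out)
  attr(res, "stats") <- stats_as_list(stats)
  res
}

#' All similar pairs across two partition blocks
#'
#' Returns immediately (no member-level work) when the interval-block
#' distance of the two block keys exceeds `2 * tau`; otherwise indexes
#' `block_i` and probes every member of `block_j` whose length is within
#' `tau` of some indexed length.
#'
#' @param block_i,block_j two distinct blocks from one [fq_split()].
#' @param tau edit-distance threshold.
#' @param scheme the `interval_scheme` the blocks were built under (used
#'   for block-level pruning; `NULL` disables it).
#' @param control a [join_control()].
#' @param stats optional stats environment.
#' @return a `similar_pairs` data frame.
#' @export
rs_join <- function(block_i, block_j, tau, scheme = NULL,
                    control = join_control(), stats = NULL) {
  block_i <- as_block(block_i); block_j <- as_block(block_j)
  if (is.null(stats)) stats <- new_join_stats()
  stats$rs_tasks <- stats$rs_tasks + 1L
  if (control$use_block_prune && !is.null(scheme) &&
      !is.null(block_i$key) && !is.null(block_j$key)) {
    if (interval_block_distance(block_i$key, block_j$key, scheme) > 2L * tau) {
      stats$blocks_pruned <- stats$blocks_pruned + 1L
      res <- similar_pairs()
      attr(res, "stats") <- stats_as_list(stats)
      return(res)
    }
  }
  out <- new_pair_accumulator()
  cache_i <- block_cache(block_i); cache_j <- block_cache(block_j)
  codes <- c(cache_i$codes, cache_j$codes)
  fv <- c(cache_i$fvec, cache_j$fvec)
  join_sides(block_i$texts, block_i$ids, block_j$texts, block_j$ids,
             fv, codes, as.integer(tau), control, stats,
             self = FALSE, out = out)
  res <- acc_pairs(out)
  attr(res, "stats") <- stats_as_list(stats)
  res
}

as_block <- function(x) {
  if (is.list(x) && !is.null(x$ids)) {
    if (is.null(x$fvec)) {
      # degenerate single-group frequency vector (string length): enough
      # for the L1 filter to stay sound
      x$fvec <- matrix(nchar(x$texts), ncol = 1L)
    }
    return(x)
  }
  texts <- collection_texts(x)
  list(key = NULL, ids = collection_ids(x), texts = texts,
       fvec = matrix(nchar(texts), ncol = 1L))
}

#' Run the complete blocked join schedule
#'
#' Task `j` computes the self-join of block `j` plus the cross-join of
#' every earlier block `i < j` with block `j`; the union over tasks is the
#' full similar-pair set. Every unordered block pair is processed exactly
#' once and every string pair verified at most once, so the schedule is
#' complete and duplicate-free; the result is identical for any worker
#' count.
#'
#' @param blocks blocks from [fq_split()].
#' @param tau edit-distance threshold.
#' @param workers number of parallel workers (>= 1). Tasks are pure; with
#'   `workers > 1` they run via [parallel::mclapply()].
#' @param control a [join_control()].
#' @return `similar_pairs` with a `stats` attribute (summed counters).
#' @export
schedule_and_run <- function(blocks, tau, workers = 1L,
                             control = join_control()) {
  workers <- as.integer(workers)
  if (workers < 1L) stop("workers must be >= 1")
  scheme <- attr(blocks, "scheme")
  nb <- length(blocks)
  task <- function(j) {
    stats <- new_join_stats()
    pieces <- vector("list", j)
    pieces[[j]] <- self_join(blocks[[j]], tau, control, stats)
    for (i in seq_len(j - 1L))
      pieces[[i]] <- rs_join(blocks[[i]], blocks[[j]], tau, scheme,
                             control, stats)
    list(pairs = combine_pairs(pieces), stats = stats_as_list(stats))
  }
  results <- if (workers == 1L) {
    lapply(seq_len(nb), task)
  } else {
    res <- parallel::mclapply(seq_len(nb), task, mc.cores = workers)
    bad <- vapply(res, inherits, NA, "try-error")
    if (any(bad)) stop("worker task failed: ", as.character(res[[which(bad)[1L]]]))
    res
  }
  pairs <- combine_pairs(lapply(results, `[[`, "pairs"))
  all_stats <- lapply(results, `[[`, "stats")
  summed <- Reduce(function(a, b) Map(`+`, a, b), all_stats)
  attr(pairs, "stats") <- summed
  pairs
}

#' End-to-end similarity join
#'
#' The main user-facing entry point: partitions the input, runs the
#' requested engine, and returns the canonical pair set. With `delta`
#' instead of `tau`, a per-pair threshold `floor((1 - delta) * max
#' length)` applies: the join runs at the largest per-pair threshold the
#' collection admits and pairs are then re-checked against their own
#' threshold.
#'
#' @param collection a [string_collection()], character vector, or file
#'   path (read as `lines`).
#' @param tau global edit-distance threshold (mutually exclusive with
#'   `delta`).
#' @param delta normalized similarity threshold in `[0, 1]`.
#' @param engine `"para"` (blocked schedule), `"pada"` (staged dataflow)
#'   or `"brute"` (oracle).
#' @param g,bins alphabet groups and intervals per group for partitioning.
#' @param partition,scheme explicit overrides (see [as_alphabet_partition()]
#'   and [as_interval_scheme()]).
#' @param workers parallel workers for the blocked schedule.
#' @param control a [join_control()].
#' @return `similar_pairs` with a `stats` attribute where the engine
#'   provides one.
#' @examples
#' similarity_join(c("kitten", "sitting", "mitten"), tau = 1)
#' @export
similarity_join <- function(collection, tau = NULL, delta = NULL,
                            engine = c("para", "pada", "brute"),
                            g = 3L, bins = 4L,
                            partition = NULL, scheme = NULL,
                            workers = 1L, control = join_control()) {
  engine <- match.arg(engine)
  if (is.null(tau) == is.null(delta))
    stop("exactly one of tau and delta must be given")
  if (is.character(collection) && length(collection) == 1L &&
      file.exists(collection))
    collection <- read_collection(collection)
  texts <- collection_texts(collection)
  ids <- collection_ids(collection)
  if (!is.null(delta)) {
    if (delta < 0 || delta > 1) stop("delta must be within [0, 1]")
    max_len <- max(nchar(texts))
    tau_run <- delta_to_tau(delta, max_len, max_len)
  } else {
    tau_run <- as.integer(tau)
    if (tau_run < 0L) stop("tau must be >= 0")
  }
  res <- switch(engine,
    brute = brute_force_join(collection, tau_run),
    pada = run_padaflow(collection, tau_run, g = g, partition = partition,
                        control = control),
    para = {
      blocks <- fq_split(collection, partition = partition, scheme = scheme,
                         g = g, bins = bins)
      schedule_and_run(blocks, tau_run, workers = workers, control = control)
    })
  if (!is.null(delta)) {
    lens <- nchar(texts); names(lens) <- as.character(ids)
    per_tau <- delta_to_tau(delta,
                            lens[as.character(res$id_a)],
                            lens[as.character(res$id_b)])
    keep <- res$edit_distance <= per_tau
    st <- attr(res, "stats")
    res <- similar_pairs(res$id_a[keep], res$id_b[keep],
                         res$edit_distance[keep])
    attr(res, "stats") <- st
  }
  res
}
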