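#' Per-symbol frequency variance across a collection
#'
#' For every symbol occurring in the collection, computes the population
#' variance of its per-string occurrence count (strings where the symbol is
#' absent contribute a count of 0). High-variance symbols carry the most
#' information for partitioning, so the collapsing step balances variance
#' mass across groups.
#'
#' @param collection a [string_collection()] or character vector.
#' @param alphabet optional symbols to tabulate over (default: every
#'   symbol occurring in the collection); symbols absent everywhere get
#'   variance 0.
#' @return named numeric vector, one entry per symbol, sorted by symbol.
#' @export
symbol_variance <- function(collection, alphabet = NULL) {
  texts <- collection_texts(collection)
  if (length(texts) == 0L) stop("cannot compute symbol statistics: empty collection")
  chars <- strsplit(texts, "", fixed = TRUE)
  observed <- sort(unique(unlist(chars, use.names = FALSE)))
  alphabet <- if (is.null(alphabet)) observed
              else sort(unique(c(expand_alphabet(alphabet), observed)))
  n <- length(texts)
  counts <- vapply(chars, function(cc) {
    tabulate(factor(cc, levels = alphabet), nbins = length(alphabet))
  }, integer(length(alphabet)))
  counts <- matrix(counts, nrow = length(alphabet))
  mu <- rowMeans(counts)
  v <- rowSums((counts - mu)^2) / n   # population variance
  names(v) <- alphabet
  v
}

#' Collapse an alphabet into g symbol groups by zigzag dealing
#'
#' Symbols are sorted by decreasing weight (typically the per-symbol
#' frequency variance from [symbol_variance()], ties broken by symbol) and
#' dealt into `g` groups in boustrophedon order (1..g, g..1, 1..g, ...) so
#' that each group receives a balanced share of the weight mass. An
#' explicit `groups` override bypasses the heuristic entirely and is used
#' verbatim (after validation), which makes externally specified group
#' memberships reproducible bit-exactly.
#'
#' @param weights named numeric vector of per-symbol weights (e.g.
#'   variances, or total counts).
#' @param g number of groups (>= 1, <= alphabet size).
#' @param groups optional explicit override: list of character vectors
#'   (each a set of single symbols), or a vector of strings whose
#'   characters are the group members.
#' @return An `alphabet_partition`: a list of `g` character vectors of
#'   symbols, pairwise disjoint, jointly covering the weighted alphabet.
#' @export
z_collapse <- function(weights, g = 3L, groups = NULL) {
  if (!is.null(groups)) return(as_alphabet_partition(groups))
  if (length(weights) == 0L) stop("empty weight table")
  g <- as.integer(g)
  if (g < 1L) stop("g must be >= 1")
  if (g > length(weights))
    stop(sprintf("g = %d exceeds alphabet size %d", g, length(weights)))
  ord <- order(-weights, names(weights))
  syms <- names(weights)[ord]
  # boustrophedon deal: 1..g, g..1, 1..g, ...
  lane <- rep_len(c(seq_len(g), rev(seq_len(g))), length(syms))
  out <- split(syms, lane)[as.character(seq_len(g))]
  names(out) <- NULL
  as_alphabet_partition(out)
}

#' Coerce to an alphabet partition
#'
#' @param x a list of character vectors of symbols, or a character vector
#'   where each element's characters form one group.
#' @return validated `alphabet_partition` object.
#' @export
as_alphabet_partition <- function(x) {
  if (inherits(x, "alphabet_partition")) return(x)
  if (is.character(x)) x <- strsplit(x, "", fixed = TRUE)
  if (!is.list(x) || length(x) == 0L) stop("partition must be a non-empty list of symbol sets")
  x <- lapply(x, function(gr) unique(as.character(gr)))
  all_syms <- unlist(x, use.names = FALSE)
  if (anyDuplicated(all_syms))
    stop("alphabet groups must be pairwise disjoint; duplicated symbol(s): ",
         paste(unique(all_syms[duplicated(all_syms)]), collapse = ", "))
  structure(x, class = "alphabet_partition")
}

#' @export
print.alphabet_partition <- function(x, ...) {
  cat(sprintf("<alphabet_partition: %d group(s)>\n", length(x)))
  for (k in seq_along(x))
    cat(sprintf("  group %d: {%s}\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}

#' Joint-frequency vector of a string
#'
#' Component k counts the positions of `text` whose symbol belongs to
#' group k of the partition. When the partition covers every symbol of the
#' text, the components sum to the string length; symbols in no group are
#' not counted anywhere and are reported once via a warning.
#'
#' @param text a single string (may be empty: all-zero vector).
#' @param partition an `alphabet_partition`.
#' @return integer vector of length `length(partition)`.
#' @export
joint_frequency <- function(text, partition) {
  partition <- as_alphabet_partition(partition)
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  f <- vapply(partition, function(gr) sum(chars %in% gr), 0L)
  uncovered <- setdiff(chars, unlist(partition, use.names = FALSE))
  if (length(uncovered) > 0L)
    warning("symbol(s) not covered by any alphabet group (not counted): ",
            paste(sort(uncovered), collapse = ", "))
  f
}

# vectorised over a collection -> n x g integer matrix
joint_frequency_matrix <- function(texts, partition) {
  partition <- as_alphabet_partition(partition)
  chars <- strsplit(texts, "", fixed = TRUE)
  g <- length(partition)
  sym2grp <- integer(0)
  for (k in seq_len(g)) {
    v <- rep.int(k, length(partition[[k]]))
    names(v) <- partition[[k]]
    sym2grp <- c(sym2grp, v)
  }
  t(vapply(chars, function(cc) {
    grp <- sym2grp[cc]
    tabulate(grp[!is.na(grp)], nbins = g)
  }, integer(g)))
}

#' Build per-group count intervals by equal-frequency cuts
#'
#' For each alphabet group, splits the observed range of joint-frequency
#' counts into at most `bins` contiguous integer intervals using discrete
#' (type 1) quantile cut points, merging duplicate boundaries. The
#' resulting intervals are non-overlapping, sorted, and cover every count
#' observed in the collection the vectors came from. An explicit
#' user-supplied scheme (see [as_interval_scheme()]) bypasses this builder.
#'
#' @param fvecs matrix of joint-frequency vectors (rows = strings) or a
#'   list of integer vectors.
#' @param bins target number of intervals per group (scalar or per-group).
#' @return An `interval_scheme`: a list with one two-column matrix
#'   (`lo`, `hi`) per group.
#' @export
build_interval_scheme <- function(fvecs, bins = 4L) {
  if (is.list(fvecs)) fvecs <- do.call(rbind, fvecs)
  fvecs <- as.matrix(fvecs)
  if (nrow(fvecs) == 0L) stop("need at least one frequency vector")
  g <- ncol(fvecs)
  bins <- rep_len(as.integer(bins), g)
  if (any(bins < 1L)) stop("bins must be >= 1 for every group")
  scheme <- vector("list", g)
  for (k in seq_len(g)) {
    counts <- fvecs[, k]
    distinct <- sort(unique(counts))
    b <- min(bins[k], length(distinct))
    # discrete quantile upper boundaries; duplicates collapse
    hi <- unique(as.integer(quantile(counts, probs = seq_len(b) / b, type = 1)))
    hi[length(hi)] <- max(distinct)
    lo <- c(min(distinct), utils::head(hi, -1L) + 1L)
    keep <- lo <= hi
    scheme[[k]] <- cbind(lo = lo[keep], hi = hi[keep])
  }
  as_interval_scheme(scheme)
}

#' Coerce to an interval scheme
#'
#' @param x a list with one element per group: either a two-column matrix
#'   of `lo`, `hi` bounds or a character vector of `"lo-hi"` strings.
#' @return validated `interval_scheme`.
#' @export
as_interval_scheme <- function(x) {
  if (inherits(x, "interval_scheme")) return(x)
  if (!is.list(x) || length(x) == 0L) stop("scheme must be a non-empty list")
  x <- lapply(x, function(iv) {
    if (is.character(iv)) {
      parts <- strsplit(iv, "-", fixed = TRUE)
      iv <- cbind(lo = as.integer(vapply(parts, `[`, "", 1L)),
                  hi = as.integer(vapply(parts, `[`, "", 2L)))
    }
    iv <- matrix(as.integer(iv), ncol = 2L, dimnames = list(NULL, c("lo", "hi")))
    if (any(iv[, 1L] > iv[, 2L])) stop("interval lo > hi")
    if (is.unsorted(iv[, 1L], strictly = TRUE) ||
        any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      stop("intervals within a group must be sorted and non-overlapping")
    iv
  })
  structure(x, class = "interval_scheme")
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf("<interval_scheme: %d group(s)>\n", length(x)))
  for (k in seq_along(x))
    cat(sprintf("  group %d: %s\n", k,
                paste(sprintf("[%d,%d]", x[[k]][, 1L], x[[k]][, 2L]),
                      collapse = " ")))
  invisible(x)
}

#' Interval vector of a joint-frequency vector
#'
#' Component k is the 1-based rank of the group-k interval containing
#' count k. Errors if a count falls outside every interval of its group
#' (which happens when a scheme built on a different collection is reused).
#'
#' @param fvec integer joint-frequency vector.
#' @param scheme an `interval_scheme`.
#' @return integer vector of 1-based interval indices.
#' @export
interval_vector <- function(fvec, scheme) {
  scheme <- as_interval_scheme(scheme)
  if (length(fvec) != length(scheme))
    stop("frequency vector and scheme have different group counts")
  vapply(seq_along(fvec), function(k) {
    iv <- scheme[[k]]
    hit <- which(fvec[k] >= iv[, 1L] & fvec[k] <= iv[, 2L])
    if (length(hit) != 1L)
      stop(sprintf("count %d of group %d is outside every interval of the scheme",
                   fvec[k], k))
    hit
  }, 0L)
}

#' Split a collection into disjoint partition blocks
#'
#' Each block contains all strings sharing one interval vector under the
#' given alphabet partition and interval scheme. Blocks are disjoint, their
#' union is the whole collection, and they are the unit of parallel work
#' for the blocked join schedule.
#'
#' @param collection a [string_collection()] or character vector.
#' @param partition an `alphabet_partition` (default: built by
#'   [z_collapse()] on [symbol_variance()] with `g` groups).
#' @param scheme an `interval_scheme` (default: built by
#'   [build_interval_scheme()] with `bins` intervals per group).
#' @param g,bins defaults for the built partition/scheme.
#' @return list of blocks; each block is a list with `key` (interval
#'   vector), `ids` (0-based string ids) and `fvec` matrix rows cached for
#'   the members. Blocks are ordered by key for determinism.
#' @export
fq_split <- function(collection, partition = NULL, scheme = NULL,
                     g = 3L, bins = 4L) {
  texts <- collection_texts(collection)
  ids <- collection_ids(collection)
  if (is.null(partition)) {
    v <- symbol_variance(texts)
    partition <- z_collapse(v, g = min(as.integer(g), length(v)))
  }
  partition <- as_alphabet_partition(partition)
  fmat <- joint_frequency_matrix(texts, partition)
  if (is.null(scheme)) scheme <- build_interval_scheme(fmat, bins = bins)
  scheme <- as_interval_scheme(scheme)
  vmat <- t(apply(fmat, 1L, interval_vector, scheme = scheme))
  if (length(partition) == 1L) vmat <- matrix(vmat, ncol = 1L)
  keys <- apply(vmat, 1L, paste, collapse = ",")
  order_keys <- sort(unique(keys))
  blocks <- lapply(order_keys, function(kk) {
    idx <- which(keys == kk)
    list(key = vmat[idx[1L], ],
         ids = ids[idx],
         texts = texts[idx],
         fvec = fmat[idx, , drop = FALSE])
  })
  attr(blocks, "partition") <- partition
  attr(blocks, "scheme") <- scheme
  blocks
}

#' Convert a similarity threshold to an edit-distance threshold
#'
#' A normalized similarity delta in `[0, 1]` corresponds to an integral
#' edit-distance threshold `tau = floor((1 - delta) * max(len_s, len_r))`;
#' the floor is conservative because edit distance is integral.
#'
#' @param delta similarity threshold in `[0, 1]`.
#' @param len_s,len_r the two string lengths (>= 1). Vectorised.
#' @return non-negative integer threshold(s).
#' @export
delta_to_tau <- function(delta, len_s, len_r) {
  if (any(delta < 0) || any(delta > 1)) stop("delta must be within [0, 1]")
  if (any(len_s < 1L) || any(len_r < 1L)) stop("string lengths must be >= 1")
  # epsilon guards against binary round-off in (1 - delta) * max length
  as.integer(floor((1 - delta) * pmax(len_s, len_r) + 1e-9))
}

collection_texts <- function(x) {
  if (inherits(x, "string_collection")) x$text else as.character(x)
}

collection_ids <- function(x) {
  if (inherits(x, "string_collection")) as.integer(x$id)
  else seq_along(x) - 1L
}
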