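#' Length filter
#'
#' Two strings within edit distance tau cannot differ in length by more
#' than tau. Vectorised necessary condition; never rejects a true pair.
#'
#' @param len_s,len_r string lengths (>= 1).
#' @param tau edit-distance threshold (>= 0).
#' @return logical: TRUE when the pair survives.
#' @export
length_filter <- function(len_s, len_r, tau) {
  abs(len_s - len_r) <= tau
}

# Segment lengths of the even tau+1 partition of a length-l string:
# with k = l mod (tau+1), the first tau+1-k segments get floor(l/(tau+1))
# and the last k get the ceiling (remainder pushed to the tail).
segment_layout <- function(l, tau) {
  p <- tau + 1L
  base <- l %/% p
  k <- l %% p
  lens <- c(rep.int(base, p - k), rep.int(base + 1L, k))
  starts <- cumsum(c(0L, lens[-p]))
  cbind(start = as.integer(starts), len = as.integer(lens))
}

#' Split a string into tau+1 disjoint segments
#'
#' Pigeonhole segmentation: any string within edit distance tau of `text`
#' must contain at least one of these segments verbatim. Uses the even
#' partition (longer segments at the tail). Strings shorter than tau+1
#' cannot be segmented and are classified as too short (`NULL` return, to
#' be verified exhaustively against length-compatible candidates).
#'
#' @param text a single string.
#' @param tau edit-distance threshold (>= 0).
#' @return data frame with columns `ordinal` (1-based), `start` (0-based),
#'   `len`, `segment`; or `NULL` when `nchar(text) < tau + 1`.
#' @export
partition_segments <- function(text, tau) {
  stopifnot(length(text) == 1L, tau >= 0L)
  l <- nchar(text)
  if (l < tau + 1L) return(NULL)
  lay <- segment_layout(l, as.integer(tau))
  data.frame(
    ordinal = seq_len(tau + 1L),
    start = lay[, "start"],
    len = lay[, "len"],
    segment = substring(text, lay[, "start"] + 1L, lay[, "start"] + lay[, "len"]),
    stringsAsFactors = FALSE
  )
}

#' Multi-match-aware substring window
#'
#' For segment `i` (of tau+1) of an indexed string `s`, starting at `p_i`
#' with length `n`, returns the inclusive 0-based range of start positions
#' in a probe string `r` where that segment can occur if `Ed(s, r) <= tau`:
#' the window is bounded by the segment-ordinal shifts `p_i +/- (i - 1)`
#' and the length-difference shifts `p_i + delta -/+ (tau + 1 - i)`, clipped
#' to valid starts `[0, len_r - n]`. Completeness (some segment of `s`
#' matches inside its window for every true pair) is established by
#' exhaustive oracle tests rather than trusted from a closed form.
#'
#' @param i segment ordinal, 1..tau+1.
#' @param p_i 0-based start of the segment in the indexed string.
#' @param n segment length.
#' @param len_r probe string length.
#' @param delta signed length difference `len_r - len_s`.
#' @param tau edit-distance threshold.
#' @return integer `c(lo, hi)`; empty window (no candidate starts) is
#'   signalled by `lo > hi`.
#' @export
substring_window <- function(i, p_i, n, len_r, delta, tau) {
  lo <- max(0L, p_i - (i - 1L), p_i + delta - (tau + 1L - i))
  hi <- min(len_r - n, p_i + (i - 1L), p_i + delta + (tau + 1L - i))
  c(lo = as.integer(lo), hi = as.integer(hi))
}

#' L1 frequency-vector filter
#'
#' One edit operation changes the joint-frequency vector by at most 2 in
#' L1 norm, so similar strings (Ed <= tau) satisfy
#' `sum(abs(f1 - f2)) <= 2 * tau`.
#'
#' @param f1,f2 joint-frequency vectors of equal length.
#' @param tau edit-distance threshold.
#' @return logical: TRUE when the pair survives.
#' @export
frequency_prune <- function(f1, f2, tau) {
  if (length(f1) != length(f2))
    stop("frequency vectors have different lengths")
  sum(abs(f1 - f2)) <= 2 * tau
}

#' Lower bound on frequency distance between two partition blocks
#'
#' Given two interval vectors under one scheme, sums the per-group gaps
#' between the indexed intervals: `gap([a,b],[c,d]) = max(0, c-b, a-d)`.
#' This is a provable lower bound on the L1 distance of the joint-frequency
#' vectors of any pair of member strings, so block pairs with a bound
#' greater than `2 * tau` are safely skipped without looking at members.
#'
#' @param v1,v2 interval vectors (1-based indices into `scheme`).
#' @param scheme an `interval_scheme`.
#' @return non-negative integer lower bound.
#' @export
interval_block_distance <- function(v1, v2, scheme) {
  scheme <- as_interval_scheme(scheme)
  if (length(v1) != length(scheme) || length(v2) != length(scheme))
    stop("interval vectors and scheme have different group counts")
  total <- 0L
  for (k in seq_along(scheme)) {
    iv <- scheme[[k]]
    if (v1[k] < 1L || v1[k] > nrow(iv) || v2[k] < 1L || v2[k] > nrow(iv))
      stop(sprintf("interval index out of range for group %d", k))
    a <- iv[v1[k], ]; b <- iv[v2[k], ]
    total <- total + max(0L, b[1L] - a[2L], a[1L] - b[2L])
  }
  as.integer(total)
}
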