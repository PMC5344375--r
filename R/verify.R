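#' Threshold-bounded banded edit distance
#'
#' Computes the exact Levenshtein distance between `s` and `r` when it is
#' at most `tau`, restricting the dynamic program to the +/- tau diagonal
#' band with row-min early termination, so the work is
#' O((2 tau + 1) * min(|s|, |r|)) instead of O(|s| * |r|). Unit costs for
#' insertion, deletion and substitution; symbols are Unicode code points.
#'
#' @param s,r strings, or integer code-point vectors (as from
#'   [utf8ToInt()]).
#' @param tau edit-distance threshold (>= 0).
#' @return list with `distance` (integer, `NA` when the distance exceeds
#'   `tau`), `exceeds` (logical) and `cells` (DP cells touched; always
#'   `<= (2 tau + 1) * (min(|s|, |r|) + 1)`).
#' @examples
#' edit_distance_banded("kitten", "sitting", 3)
#' @export
edit_distance_banded <- function(s, r, tau) {
  a <- as_codepoints(s)
  b <- as_codepoints(r)
  res <- .ed_banded_int(a, b, as.integer(tau))
  list(distance = if (res[1L] < 0L) NA_integer_ else res[1L],
       exceeds = res[1L] < 0L,
       cells = res[2L])
}

as_codepoints <- function(x) {
  if (is.integer(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) integer(0) else utf8ToInt(x)
}

#' Extension-based verification around a matched segment
#'
#' Given a candidate pair where segment `i` of `s` (start `p_i`, length
#' `n`) matches `r` at start `q` verbatim, verifies the pair by the
#' decomposition Ed(left) + Ed(segment) + Ed(right) <= tau: the left parts
#' `s[0, p_i)` vs `r[0, q)` are verified first under the budget
#' `min(tau, (i - 1) + |q - p_i|)` implied by the segment ordinal, and the
#' right parts get whatever budget the left's actual distance leaves. The
#' decomposition can overestimate the true distance, so this is a fast
#' reject layer: a rejection here is revisited by nothing, but an
#' acceptance is always confirmed with a full banded verification by the
#' join engines.
#'
#' @param s,r the two strings.
#' @param i segment ordinal (1-based, of tau+1).
#' @param p_i 0-based segment start in `s`.
#' @param n segment length.
#' @param q 0-based start of the match in `r`.
#' @param tau edit-distance threshold.
#' @return list with `distance` (the decomposition's total, `NA` when it
#'   exceeds `tau`), `exceeds`, and `cells`.
#' @export
extension_verify <- function(s, r, i, p_i, n, q, tau) {
  a <- as_codepoints(s)
  b <- as_codepoints(r)
  seg_a <- a[seq_len(n) + p_i]
  seg_b <- b[seq_len(n) + q]
  if (!identical(seg_a, seg_b))
    stop("precondition violated: r(q, n) must equal s(p_i, n)")
  left_a <- a[seq_len(p_i)]
  left_b <- b[seq_len(q)]
  # ordinal bound: at most i-1 edits can fall left of segment i, but the
  # start shift |q - p_i| forces at least that many; cap at tau
  left_budget <- min(tau, (i - 1L) + abs(q - p_i))
  left <- .ed_banded_int(left_a, left_b, as.integer(left_budget))
  cells <- left[2L]
  if (left[1L] < 0L)
    return(list(distance = NA_integer_, exceeds = TRUE, cells = cells))
  right_budget <- tau - left[1L]
  right_a <- if (p_i + n < length(a)) a[(p_i + n + 1L):length(a)] else integer(0)
  right_b <- if (q + n < length(b)) b[(q + n + 1L):length(b)] else integer(0)
  right <- .ed_banded_int(right_a, right_b, as.integer(right_budget))
  cells <- cells + right[2L]
  if (right[1L] < 0L)
    return(list(distance = NA_integer_, exceeds = TRUE, cells = cells))
  list(distance = left[1L] + right[1L], exceeds = FALSE, cells = cells)
}
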