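---
title: "Partition-based edit-distance similarity join: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-based edit-distance similarity join: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segjoin)
```

## The problem

A similarity self-join under edit distance asks, for a collection of $n$
strings and a threshold $\tau$, for every unordered pair $(s, r)$ with
$\mathrm{Ed}(s, r) \le \tau$, where $\mathrm{Ed}$ is the Levenshtein
distance with unit costs for insertion, deletion and substitution. Naive
evaluation needs $\binom{n}{2}$ full DP computations; segjoin reduces this
with a stack of *necessary-condition* filters so that expensive
verification runs only on a small candidate set, while guaranteeing the
output is exactly the naive answer. All guarantees in this vignette are
backed by tests against an independent oracle (`utils::adist`, base R's
full-matrix DP) rather than trusted from derivations.

## Frequency signatures and partitioning

The alphabet is collapsed into $g$ groups $\Sigma_1 \ldots \Sigma_g$. The
*joint-frequency vector* $f(s) \in \mathbb{N}^g$ counts, per group, the
positions of $s$ holding a symbol of that group; when the groups cover the
string's symbols, $\sum_k f(s)_k = |s|$. The load-bearing property is:

> one edit operation changes $\|f(s)\|$ by at most 2 in $L_1$
> (a substitution decrements one component and increments another;
> insertion/deletion changes one component by one and the length by one),
> hence $\mathrm{Ed}(s,r) \le \tau \Rightarrow \|f(s) - f(r)\|_1 \le 2\tau$.

This bound holds for *any* grouping, so the grouping only affects pruning
power, never correctness. We deal symbols into groups in boustrophedon
("zigzag") order of decreasing per-string count variance (1..g, g..1, …),
balancing variance mass; ties are broken alphabetically for determinism.
Variance is the population variance of per-string occurrence counts,
counting 0 for strings lacking the symbol. The collapsing heuristic was a
genuinely open design point; the zigzag deal is the simplest balanced
assignment and is overridable with a verbatim group file, which is also how
the documentation's worked example reproduces its printed groups exactly.

Each group's observed counts are then cut into at most $b$ contiguous
integer intervals by discrete (type-1) quantile boundaries, merged on
duplicates — equal-frequency cuts keep the resulting blocks balanced under
skewed count distributions, which equal-width cuts do not. The *interval
vector* $v(s)$ holds the per-group index of the interval containing
$f(s)_k$; strings with identical $v$ form one *block*. Blocks are disjoint
and cover the collection. For two blocks, summing the per-group gaps
between the indexed intervals ($\mathrm{gap}([a,b],[c,d]) = \max(0, c-b,
a-d)$) lower-bounds the $L_1$ distance of any member pair, so block pairs
with bound $> 2\tau$ are skipped without touching members.

Defaults: $g = 3$ groups, $b = 4$ intervals per group (matching the
worked example's configuration; both are exposed as `g` and `bins`). For
alphabets smaller than $g$ (DNA with $g=3$ works; a binary alphabet does
not), the default path caps $g$ at the alphabet size. Tuning $g$ and $b$
from data is out of scope.

## Candidate generation

Within and across blocks the join is index-probe. Each indexed string of
length $\ell \ge \tau + 1$ is split into $\tau+1$ disjoint segments (even
partition: remainder lengths go to the tail); by pigeonhole, any string
within distance $\tau$ contains at least one segment verbatim. Segments
are keyed by (length, ordinal, text) in an inverted index. A probe string
$r$ enumerates, for each indexed length within $\tau$ of $|r|$ and each
ordinal $i$, the *multi-match-aware window* of start positions

$$[\,\max(0,\; p_i-(i-1),\; p_i+\Delta-(\tau+1-i)),\;
   \min(|r|-n,\; p_i+(i-1),\; p_i+\Delta+(\tau+1-i))\,]$$

with $\Delta = |r| - \ell$ signed and all coordinates 0-based, and looks up
the corresponding substrings of $r$. The ordinal shift $\pm(i-1)$ bounds
how far edits before segment $i$ can move its match; the $\Delta \mp
(\tau+1-i)$ terms bound the remaining shift the right-hand side can absorb.
Window completeness — every true pair produces at least one in-window
segment match — is asserted exhaustively over all binary strings of length
$\le 6$ for $\tau \in \{1,2\}$ and on planted-pair suites, because printed
forms of these bounds in the literature are inconsistent and we prefer an
oracle-checked reconstruction to a trusted formula.

Strings shorter than $\tau+1$ cannot be segmented; they are set aside at
indexing time and verified directly against every length-compatible probe.
This path is rare (it exists mostly for stress tests with very short
strings) and is covered by the same equivalence tests.

## Verification

Candidates are confirmed in two layers.

*Extension pre-reject.* At a segment-match hit $(i, q)$ the pair splits
into left parts, the matched segment (distance 0), and right parts. The
left parts are verified under the budget $\min(\tau,\, (i-1) + |q - p_i|)$
and the right parts under $\tau$ minus the left's actual distance. The
composition can overestimate the true distance at a particular hit, so a
rejection only discards *that hit*, never the pair: the pair survives to
its other segment-match hits. For a true pair, the hit at the last clean
segment of an optimal alignment always passes (segments after it each
carry at least one edit, leaving at most $i-1$ edits on the left), so no
true pair is lost — also verified by a dedicated property test.

*Banded DP.* Final acceptance always comes from a full banded
verification: DP cells restricted to the $\pm\tau$ diagonal band, rows
swapped so the band runs over the shorter string, early termination when a
whole band row exceeds $\tau$. The implementation (C++ via Rcpp) returns
the exact distance when $\le \tau$, a sentinel otherwise, and an
instrumentation counter of cells touched that the tests bound by
$(2\tau+1)(\min(|s|,|r|)+1)$ on every call. Each candidate pair is
verified at most once per probe (a per-probe decided-set; the frequency
filter may also decide a pair, which is sound because that filter is
hit-independent).

## The schedule and the dataflow engine

Blocks $S_1 \ldots S_m$ are ordered deterministically by interval-vector
key. Task $j$ computes the self-join of $S_j$ plus the cross-join
$S_i \times S_j$ for all $i < j$: every unordered block pair is processed
exactly once (the tests count tasks: $m$ self, $\binom{m}{2}$ cross), and
within a task every string pair at most once — self-joins index members in
decreasing length order (ties by id) and let a probe pair only with
strings indexed before it. Tasks share no state, so the executor is
irrelevant to the result; `workers > 1` uses `parallel::mclapply` and the
tests require byte-identical output files for 1 vs 8 workers. Task $j$
performs $j$ cross-joins, so later tasks carry more work; this is a known
load-imbalance (performance, not correctness) that we do not rebalance.

The second engine (`engine = "pada"`) keeps the same verification but
replaces interval-vector blocking with grouping by *exact* frequency
vector, generating candidates from group-key pairs within $L_1 \le 2\tau$
(an ordered double loop $j \ge i$, so each group pair is emitted once at
the source, including each group with itself). It mirrors, stage for
stage, a distributed dataflow — token counting is a flatMap/reduceByKey,
vector grouping a groupByKey, candidate generation a mapPartitions over a
broadcast read-only group list, verification a join back to the string
table — but runs single-node and deterministically so the distributed
semantics are testable without a cluster. Cluster deployment itself is out
of scope. Both engines and the brute-force oracle must return identical
pair sets on every test collection; this three-way equivalence is the
package's central acceptance property.

## Thresholds, ties, degenerate inputs

* $\delta$-mode: a normalized similarity $\delta$ maps to
  $\tau = \lfloor (1-\delta) \cdot \max(|s|,|r|) \rfloor$ per pair (floor,
  because edit distance is integral and the bound is an upper bound); an
  epsilon of $10^{-9}$ absorbs binary round-off so $\delta = 0.8$ at
  length 10 yields exactly 2. The join runs once at the collection-wide
  maximal $\tau$ and re-checks each output pair against its own $\tau$.
* Output is canonical: pairs $(\mathrm{id}_a < \mathrm{id}_b)$ with exact
  distance, sorted, deduplicated; ids are 0-based input order.
* Empty strings are rejected by the collection constructor (every record
  has length $\ge 1$); the verifier itself handles empty operands (used
  internally by the extension split, where left/right parts may be empty).
* An interval scheme built on one collection errors, by design, when
  applied to counts it does not cover rather than silently clamping.

## The synthetic generator and what tests do (not) show

Test collections are uniform random strings (lengths uniform in a range,
symbols uniform over the alphabet) plus planted near-duplicates produced
by $k$ uniform random edits (substitution resamples until the symbol
changes; deletion on an empty string becomes an insertion), recorded with
their script length so $\mathrm{Ed} \le k$ is checkable. Seeded
generation is reproducible to the byte. The equivalence suites run on 20
seeded collections of 300 strings, lengths 20–40, over both a 4-letter
(DNA-like) and the 26-letter alphabet, at $\tau \in \{1,2,3\}$; the
verifier suite uses $10^4$ random pairs at $\tau \in \{0..5\}$ and string
lengths up to 60. These sizes exercise every code path (multiple blocks,
cross-block pruning, short-string fallback) while keeping the suite quick.

Uniform strings are the *hardest* case for frequency-based pruning (real
text and DNA have skewed symbol distributions that partition better), but
they under-represent clustered near-duplicates: real collections have
similarity structure that changes performance, not correctness. Passing
tests therefore certify exactness of the result set on any input, and say
nothing about wall-clock behavior on a particular corpus. Realistic typo
or sequencing-error models are deliberately not modeled.

## Known limitations

* Collections must fit in memory; there is no streaming path.
* The guard on the brute-force oracle (2000 strings) limits direct
  equivalence testing, not the engines themselves.
* q-gram/prefix filtering and trie- or LSH-based methods are different
  method families and are not implemented.
* Performance of the R-level probe loop is adequate for $10^4$–$10^5$
  strings; the verifier is compiled, the orchestration is not.
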