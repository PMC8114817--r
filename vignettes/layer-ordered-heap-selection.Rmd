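---
title: "Selecting the k smallest values of X + Y with layer-ordered heaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the k smallest values of X + Y with layer-ordered heaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohsum)
```

## The problem

Given two numeric vectors $X$ and $Y$ of lengths $n_x$ and $n_y$, the
*Cartesian sum* $X + Y$ is the multiset of all $n_x n_y$ pairwise sums
$X_i + Y_j$. Top-$k$ selection asks for the $k$ smallest of those sums
without paying for all of them. The problem has a trivial
$O(n^2 \log n)$ solution (generate and sort) and an $O(n^2)$ one
(generate and $k$-select), but since reading the inputs is $\Theta(n)$
and writing the answer is $\Theta(k)$, the best possible bound is
$\Theta(n + k)$ — far below ever touching the sum matrix when
$k \ll n^2$.

This package implements an algorithm that meets the $O(n + k)$ bound
using nothing more exotic than linear-time one-dimensional rank
selection (median of medians). The practical motivation comes from mass
spectrometry: the abundance of a combined isotopologue of two molecular
fragments is the product of per-fragment isotopologue probabilities, so
on the negative-log scale abundances add, and "the $k$ most abundant
combined species" is exactly top-$k$ on a Cartesian sum
(`top_isotopologue_pairs()`).

## Layer-ordered heaps

A *layer-ordered heap* (LOH) of rank $\alpha > 1$ partitions a vector
into ascending layers $X^{(1)} \le X^{(2)} \le \cdots$: every value in
layer $u$ is $\le$ every value in layer $u+1$, while values *within* a
layer stay unordered. Layer sizes start at $|X^{(1)}| = 1$ and grow
geometrically with limiting ratio $\alpha$. This sits strictly between
a binary heap (too weak: no ordering between cousins) and a full sort
(too strong: $\Omega(n \log n)$). For any fixed $\alpha > 1$ an LOH is
built in $O(n)$ by repeatedly peeling off the largest remaining layer
with `partition_by_rank()`:

```{r}
h <- lohify(c(8, 1, 6, 4, 5, 3, 2), alpha = 2)
lapply(h$layers, sort)
```

Two concrete choices are left open by the limit-ratio definition and
fixed here as package conventions:

* **Integer layer sizes.** Layer $u$ has scheduled size
  $\lceil \alpha^{u-1} \rceil$. For $\alpha = 2$ this is the exact
  doubling schedule $1, 2, 4, 8, \ldots$; for fractional $\alpha$ it is
  one valid realization of geometric growth (`layer_size_schedule()`).
* **Remainder placement.** The final (largest-index) layer is truncated
  so sizes sum to $n$, matching the doubling construction's loop that
  caps the last layer at the number of remaining elements.

`lohify()` additionally stores, per layer, the original input positions
of its values. The selection algorithm itself never uses them, but the
isotopologue application needs to map selected sums back to (mass,
probability) pairs, and the bookkeeping costs one integer per element.

The construction peels with iterated rank selection, which is optimal
for $\alpha \ge 2$; the asymptotically better constructions needed when
$\alpha \to 1$ are out of scope here (at $\alpha = 1$ every layer is a
singleton and LOHification degenerates into sorting).

## The selection algorithm

`select_topk(x, y, k, alpha)` proceeds in four phases.

**Phase 0.** LOHify both inputs: $O(n)$.

**Phase 1.** Consider *layer products* $X^{(u)} + Y^{(v)}$, each
summarized by two corner keys computed from cached layer extrema alone:

$$\lfloor (u,v) \rfloor = (\min X^{(u)} + \min Y^{(v)},\ (u,v),\ 0),
\qquad
\lceil (u,v) \rceil = (\max X^{(u)} + \max Y^{(v)},\ (u,v),\ 1).$$

Keys are ordered lexicographically on (value, $u$, $v$, flag); the
trailing flag guarantees $\lfloor \cdot \rfloor < \lceil \cdot \rceil$
even for a product whose values are all equal, and the $(u,v)$
component makes ties deterministic. A binary min-heap seeded with
$\lfloor (1,1) \rfloor$ pops keys in ascending order. A min-corner pop
at $(u,v)$ inserts $\lfloor (u+1,v) \rfloor$, $\lfloor (u,v+1) \rfloor$
and $\lceil (u,v) \rceil$ (bounds permitting; a membership set keyed by
$(u,v,\text{flag})$ prevents duplicate insertions, exactly as in the
reference formulation — the proposal-scheme alternative that avoids the
set is deliberately not adopted). A max-corner pop *commits* the
product: its index joins the list $q$ and its area
$|X^{(u)}|\cdot|Y^{(v)}|$ accumulates into $s$. The sweep halts as soon
as $s \ge k$; the last popped value is the threshold $\tau$, an upper
bound on the $k$-th smallest sum. Because there are only
$\approx \log_\alpha^2 n$ layer products, all heap work is $o(n)$.

**Phase 2.** Any max corner still pending in the heap marks a product
whose min corner was reached — it may hold values $< \tau$ — but whose
area was never committed. Each joins $q$, accumulating area $s'$.
Pending min corners are ignored: a product whose min corner was never
popped cannot contain anything below $\tau$ (this follows from the
ascending-pop order, and is the behaviour the correctness argument
requires).

**Phase 3.** The products in $q$ are inflated into $s + s'$ candidate
sums and one linear-time $k$-selection returns the answer. Geometric
layer growth bounds the overshoot: $s < k + |X^{(u)}| |Y^{(v)}| \in
O(k)$ by phase-1 tightness, and $s' \le (\alpha^2 + 2\alpha)\,s + 1$,
so phase 3 is $O(k)$ and the whole algorithm $O(n + k)$. For the exact
doubling schedule the $\alpha = 2$ bound $s' \le 8s + 1$ holds
non-asymptotically, and the test suite asserts it on every random
instance it draws.

```{r}
x <- c(31, 5, 11, 7, 33, 6, 39, 42, 20, 0, 9, 1, 41, 26, 8)
y <- c(12, 26, 40, 9, 14, 49, 8, 2, 20, 1, 46, 43, 4, 5, 7)
sel <- select_topk(x, y, k = 14, sort_values = TRUE)
sel$values
c(s = sel$trace$s, s_prime = sel$trace$s_prime, tau = sel$trace$tau)
```

### Variants

* `select_topk_sorted_corners()` sorts all $2 L_x L_y$ corner keys up
  front and scans once, inflating on min-corner visits and counting
  area on max-corner visits. Still $\Theta(n + k)$ (the corner count is
  $o(n)$), simpler, but eager inflation makes it slower in practice
  when $k \ll n^2$.
* `select_topk_compressed()` stops after phase 2 and returns $q$
  un-inflated together with the two LOHs. Phases 0–2 cost $O(n)$
  regardless of $k$, so this gives a factored representation of a
  superset of the answer in sub-$k$ time; `inflate_candidates()` plus
  `partition_by_rank()` recovers the explicit values. Recursive
  selection *within* the compressed products is a known open direction
  and not attempted here.

### Ties, edge cases, and numerics

* **Ties at the k-th value** are resolved by count, not identity:
  exactly $k$ values come back, with duplicates of the threshold value
  filling the final slots (inherited from the tie contract of
  `partition_by_rank()`).
* **`k = 0`** returns an empty result rather than an error, and
  `partition_by_rank(x, 0)` likewise returns an empty left side: total
  functions are easier on callers iterating over $k$.
* **Output order** is unspecified (selection semantics);
  `sort_values = TRUE` requests ascending order.
* **1-based indexing.** Ranks, layer indices, and layer-pair indices
  are all 1-based, the native R convention: rank $k$ *is* the $k$-th
  smallest, and the sweep starts at layer pair $(1, 1)$.
* **Numeric domain.** Integers are exact in double precision up to
  $2^{53}$; floats are compared with ordinary IEEE semantics, and
  overflow or catastrophic cancellation in the caller's values is the
  caller's contract.
* Within-layer order and, for duplicate-heavy inputs, the layer
  membership of tied values are implementation-defined; every
  guaranteed property is stated on multisets.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 2 | Layer growth rank. Small $\alpha$ approaches sorting (expensive phase 0, tiny overshoot); large $\alpha$ cheapens LOHification but inflates more candidates for phase 3 to discard. 2 is the standard compromise and the only value with an exact integer schedule. |
| `k` | — | Number of sums requested, $0 \le k \le n_x n_y$. |
| `sort_values` | `FALSE` | Ascending output on request. |
| `record_pops` | `FALSE` | Keep the popped-key sequence in the trace for diagnostics. |

## The overshoot benchmark

`overshoot_experiment()` measures how many candidates the sweep commits
per requested value, $(s + s')/k$, over the standard grid of 15
configurations ($n \in \{1000, 2000, 4000\}$, $k$ from $n/4$ to $4n$;
`table1_configs()`). The generator draws $X$ and $Y$ as uniform random
integers; the sampling range is a design choice (the statistic is about
layer-product geometry, not value magnitudes) and defaults to
$[0, 2^{20})$ so that ties are rare at these $n$. Repetitions default
to 10, with repetition $r$ seeded as `seed + r - 1`, so configurations
sharing $n$ see identical instances within a repetition and the
LOHification is computed once per instance. Wall-clock timings are
recorded per phase but purely informational — they are
hardware-dependent and nothing asserts them. At $\alpha = 2$ the grand
mean ratio lands near 3.6–3.7: each requested sum drags roughly 2.7
extra candidates into phase 3, the price of never sorting anything.

## What the synthetic data does and does not show

Random uniform integer vectors exercise the algorithm's control flow
completely — the correctness argument is purely order-theoretic, so any
input with the same rank structure behaves identically. What they do
not emulate: heavy tie structure (real isotope tables contain near-equal
probabilities; ties only exercise the deterministic tie-breaks, which
dedicated tests cover separately), adversarial layer alignments, or the
skewed, near-geometric probability decay of real isotopologue
distributions. The isotopologue tests therefore draw random peak lists
with probabilities normalized to a sub-unit budget rather than uniform
values. Passing the suite demonstrates algorithmic correctness on all
rank structures, not domain realism of any particular distribution.

Problem sizes in the test suite are chosen so the whole suite runs in
about a minute: oracle-equivalence sweeps use $|X|, |Y| \le 25$ with
hundreds of instances (every path is compared against full enumeration,
which is only feasible at that scale), LOH property sweeps go up to
$n = 400$ across $\alpha \in \{1.5, 2, 4\}$, and the benchmark grid
runs at its full published sizes ($n$ up to 4000, $k$ up to 16000, 10
repetitions).

## Known limitations

* `select_topk()` returns values only, not the $(i, j)$ index pairs of
  each selected sum (the compressed form plus the LOHs' stored input
  positions recover pair identities where needed, as the isotopologue
  application does).
* Two vectors only; the $X_1 + \cdots + X_m$ generalization requires
  different machinery.
* No online/streaming updates: appending to $X$ or $Y$ invalidates the
  LOHs. The sorted-corners variant in particular is a one-shot scan.
* Equal-mass (isobaric) isotopologue pairs are returned as distinct
  rows; aggregating them into a convolved spectrum is a separate step
  outside this package's scope.
* The $\alpha \ll 2$ regime would need the specialized LOH
  construction; `lohify()`'s iterated peeling is optimal only for
  $\alpha \ge 2$, which is the regime used throughout.
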