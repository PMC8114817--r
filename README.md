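# lohsum

Optimal top-k selection on Cartesian sums with layer-ordered heaps.

Given two numeric vectors `X` and `Y`, `lohsum` returns the k smallest of
the `length(X) * length(Y)` pairwise sums `X[i] + Y[j]` in **O(n + k)**
time — the information-theoretic optimum — without ever materializing the
sum matrix and without any data structure fancier than linear-time rank
selection (median of medians). It is aimed at computational mass
spectrometry and at anyone who needs the best k pairs under an additive
(or, after a log transform, multiplicative) score: the package ships a
demonstration that ranks the k most abundant combined isotopologue
species of two molecular fragments.

## The method in one paragraph

Both inputs are partitioned into **layer-ordered heaps** (LOHs): ascending
layers `X^(1) <= X^(2) <= ...` whose sizes grow geometrically at rank
`alpha` (default 2: sizes 1, 2, 4, 8, ...), built in O(n) by repeatedly
peeling the largest remaining layer with `partition_by_rank()`. Each
*layer product* `X^(u) + Y^(v)` is summarized by two corner keys computed
from layer extrema alone:

    ⌊(u,v)⌋ = (min X^(u) + min Y^(v), (u,v), 0)     — min corner
    ⌈(u,v)⌉ = (max X^(u) + max Y^(v), (u,v), 1)     — max corner

A tiny priority queue sweeps the corners in ascending lexicographic order.
Popping a min corner proposes its right/upper neighbours and its own max
corner; popping a max corner commits the product's area into a running
total `s`. The sweep halts once `s >= k` (the last popped value is the
threshold `tau`, an upper bound on the k-th smallest sum); the products
whose min corner was reached but whose max corner is still pending are
collected too (area `s'`). Those committed products are guaranteed to
contain the k smallest sums, and geometric layer growth keeps
`s + s' ∈ O(k)`, so one final linear-time k-selection over the inflated
candidates finishes the job.

## Worked example

The illustrated 15-element example, selecting the k = 14 smallest sums:

```r
library(lohsum)
x <- c(31, 5, 11, 7, 33, 6, 39, 42, 20, 0, 9, 1, 41, 26, 8)
y <- c(12, 26, 40, 9, 14, 49, 8, 2, 20, 1, 46, 43, 4, 5, 7)
sel <- select_topk(x, y, k = 14, sort_values = TRUE)
sel
#> Top-14 selection on X + Y (alpha = 2)
#> phase 1: s = 17 over 6 products, tau = 10; phase 2: s' = 16; overshoot (s + s')/k = 2.357
#> values: 1 2 2 3 4 5 5 6 6 7 7 7 8 8
```

Phase 1 committed 6 layer products covering s = 17 sums before reaching
k = 14, stopping at threshold tau = 10; phase 2 added two open products
(s' = 16 more candidates), and the final k-selection kept the 14 smallest
of those 33 — out of 225 pairwise sums, 192 were never even generated.

The isotopologue demonstration, combining two carbon atoms
(¹²C 98.93 %, ¹³C 1.07 %):

```r
carbon <- isotope_peaks(c(12, 13.00335), c(0.9893, 0.0107))
top_isotopologue_pairs(carbon, carbon, k = 3)
#>       mass probability
#> 1 24.00000  0.97871449
#> 2 25.00335  0.01058551
#> 3 25.00335  0.01058551
```

The two mass-25 rows are distinct ¹²C¹³C pairs; isobaric species are
deliberately not merged (that is a separate convolution step).

A command-line front end wraps the same functions:

```sh
Rscript exec/lohsum select -x X.txt -y Y.txt -k 14 --sorted --trace
Rscript exec/lohsum lohify --input X.txt --alpha 2
Rscript exec/lohsum bench --table1 --reps 10 --seed 0
Rscript exec/lohsum isotopes -a fragA.tsv -b fragB.tsv -k 10
```

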