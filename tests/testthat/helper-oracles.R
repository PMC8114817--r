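# Brute-force oracles and small generators shared across the suite.

# k smallest pairwise sums by full enumeration + sort: the ground truth
# every selection path is compared against.
brute_topk <- function(x, y, k) {
  sort(as.vector(outer(x, y, `+`)))[seq_len(k)]
}

rand_vec <- function(n, lo = -50, hi = 50) {
  as.numeric(sample(lo:hi, n, replace = TRUE))
}

expect_same_multiset <- function(actual, expected) {
  expect_equal(sort(as.numeric(actual)), sort(as.numeric(expected)))
}

# The seven-value example vector used in the LOHify walk-through.
intro_values <- c(8, 1, 6, 4, 5, 3, 2)

# The two 15-element vectors of the illustrated k = 14 selection.
fig_x <- c(31, 5, 11, 7, 33, 6, 39, 42, 20, 0, 9, 1, 41, 26, 8)
fig_y <- c(12, 26, 40, 9, 14, 49, 8, 2, 20, 1, 46, 43, 4, 5, 7)

# Row-set equality for (u, v) index matrices, ignoring order.
expect_same_pairs <- function(actual, expected) {
  expect_setequal(paste(actual[, 1], actual[, 2]), paste(expected[, 1], expected[, 2]))
}
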