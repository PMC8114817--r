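# Checks the phased corner sweep: worked examples, brute-force oracle
# equivalence, and the ordering/coverage properties the proof of
# correctness rests on.

test_that("corner keys use layer extrema and the min/max flag tie-break", {
  hx <- lohify(fig_x, 2)
  hy <- lohify(fig_y, 2)
  ck <- corner_keys(hx, hy, 1, 1)
  expect_equal(ck$min[["value"]], 0 + 1)
  ck31 <- corner_keys(hx, hy, 3, 1)
  expect_equal(ck31$max[["value"]], 10)  # third-layer max 9 plus singleton 1
  expect_error(corner_keys(hx, hy, 5, 1), "out of bounds")

  # homogeneous layers: equal values, yet min corner sorts first via the flag
  hc <- lohify(rep(3, 4), 2)
  ckh <- corner_keys(hc, hc, 2, 2)
  expect_equal(ckh$min[["value"]], ckh$max[["value"]])
  expect_true(key_leq(ckh$min, ckh$max) && !key_leq(ckh$max, ckh$min))
})

test_that("phase 1 on the illustrated example stops at tau = 10 with s = 17", {
  hx <- lohify(fig_x, 2)
  hy <- lohify(fig_y, 2)
  p1 <- phase1_sweep(hx, hy, 14)
  expect_equal(p1$trace$tau, 10)
  expect_equal(p1$trace$s, 17)
  expect_same_pairs(
    p1$trace$q,
    cbind(c(1, 1, 2, 2, 1, 3), c(1, 2, 1, 2, 3, 1))
  )
})

test_that("k = 1 commits exactly the (1,1) product", {
  set.seed(11)
  hx <- lohify(rand_vec(20), 2)
  hy <- lohify(rand_vec(15), 2)
  p1 <- phase1_sweep(hx, hy, 1)
  expect_equal(p1$trace$s, 1)
  expect_equal(unname(p1$trace$q[1, ]), c(1L, 1L))
  expect_equal(p1$trace$tau, hx$maxs[1] + hy$maxs[1])
})

test_that("phase 2 collects the pending max corners of the illustrated example", {
  hx <- lohify(fig_x, 2)
  hy <- lohify(fig_y, 2)
  p1 <- phase1_sweep(hx, hy, 14)
  tr <- phase2_collect(p1$trace, p1$frontier)
  expect_equal(tr$s_prime, 16)
  expect_same_pairs(tr$q[tr$phase == 2, , drop = FALSE],
                    cbind(c(2, 3), c(3, 2)))
  expect_length(inflate_candidates(hx, hy, tr), 33)
})

test_that("phase 2 is empty when every product was already committed", {
  set.seed(12)
  x <- rand_vec(12); y <- rand_vec(9)
  sel <- select_topk(x, y, k = 12 * 9)
  expect_equal(sel$trace$s_prime, 0)
  expect_equal(sel$trace$s, 12 * 9)
})

test_that("inflating an area-1 product yields the single sum", {
  hx <- lohify(c(4, 9), 2)
  hy <- lohify(c(1, 7), 2)
  expect_equal(inflate_candidates(hx, hy, cbind(1L, 1L)), 4 + 1)
})

test_that("select_topk matches brute force on the illustrated example", {
  sel <- select_topk(fig_x, fig_y, k = 14, alpha = 2)
  expect_same_multiset(sel$values, brute_topk(fig_x, fig_y, 14))
})

test_that("select_topk handles the hand-checkable edge cases", {
  set.seed(13)
  expect_same_multiset(select_topk(c(1, 2), c(10, 20), 2)$values, c(11, 12))
  x <- rand_vec(10); y <- rand_vec(10)
  expect_equal(select_topk(x, y, 1)$values, min(x) + min(y))
  expect_length(select_topk(x, y, 0)$values, 0)
  expect_equal(select_topk(x, y, 5, sort_values = TRUE)$values,
               brute_topk(x, y, 5))
})

test_that("select_topk validates its contract", {
  expect_error(select_topk(numeric(0), 1, 1), "non-empty")
  expect_error(select_topk(1:3, 1:3, 10), "out of range")
  expect_error(select_topk(1:3, 1:3, -1), "out of range")
  expect_error(select_topk(1:3, 1:3, 2, alpha = 1), "alpha")
})

test_that("all selection paths agree with brute force across random instances", {
  set.seed(505)
  for (i in 1:120) {
    nx <- sample(1:25, 1); ny <- sample(1:25, 1)
    x <- rand_vec(nx, -40, 40); y <- rand_vec(ny, -40, 40)
    k <- sample(nx * ny, 1)
    expected <- brute_topk(x, y, k)
    expect_same_multiset(select_topk(x, y, k)$values, expected)
    expect_same_multiset(select_topk_sorted_corners(x, y, k)$values, expected)
    cs <- select_topk_compressed(x, y, k)
    cand <- inflate_candidates(cs$loh_x, cs$loh_y, cs$q)
    expect_same_multiset(partition_by_rank(cand, k)$left, expected)
    expect_equal(topk_comb_heap(x, y, k), expected)
    expect_same_multiset(topk_select(x, y, k), expected)
    expect_equal(topk_sort(x, y, k), expected)
  }
})

test_that("every k of a small instance is selected correctly by every path", {
  set.seed(606)
  x <- rand_vec(7, -10, 10)
  y <- rand_vec(6, -10, 10)
  for (k in seq_len(42)) {
    expected <- brute_topk(x, y, k)
    expect_same_multiset(select_topk(x, y, k)$values, expected)
    expect_same_multiset(select_topk_sorted_corners(x, y, k)$values, expected)
    expect_equal(topk_comb_heap(x, y, k), expected)
  }
})

test_that("corner keys pop in ascending order with row/column precedence", {
  set.seed(707)
  for (i in 1:40) {
    nx <- sample(2:25, 1); ny <- sample(2:25, 1)
    x <- rand_vec(nx, -20, 20); y <- rand_vec(ny, -20, 20)
    k <- sample(nx * ny, 1)
    sel <- select_topk(x, y, k, record_pops = TRUE)
    pops <- sel$trace$pops
    expect_true(pops_ascending(pops))
    expect_true(pops_precedence_ok(pops, 0))
    expect_true(pops_precedence_ok(pops, 1))
  }
})

test_that("phase 1 is tight and the candidate set covers the answer", {
  set.seed(808)
  for (i in 1:60) {
    nx <- sample(1:25, 1); ny <- sample(1:25, 1)
    x <- rand_vec(nx, -30, 30); y <- rand_vec(ny, -30, 30)
    k <- sample(nx * ny, 1)
    sel <- select_topk(x, y, k)
    tr <- sel$trace
    # s >= k, and removing the final committed product drops below k
    expect_gte(tr$s, k)
    last1 <- max(which(tr$phase == 1L))
    expect_lt(tr$s - tr$area[last1], k)
    # candidate superset of the true k smallest
    cs <- select_topk_compressed(x, y, k)
    cand <- sort(inflate_candidates(cs$loh_x, cs$loh_y, cs$q))
    expected <- brute_topk(x, y, k)
    expect_gte(length(cand), k)
    expect_true(all(cand[seq_len(k)] == expected))
    # phase-2 overshoot bound at alpha = 2
    expect_lte(tr$s_prime, 8 * tr$s + 1)
  }
})

test_that("selection is deterministic", {
  set.seed(14)
  x <- rand_vec(30); y <- rand_vec(30)
  a <- select_topk(x, y, 17)
  b <- select_topk(x, y, 17)
  expect_identical(a$values, b$values)
  expect_identical(a$trace$q, b$trace$q)
})
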