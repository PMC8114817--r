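# Linear-time one-dimensional rank selection (median of medians).
#
# This is the only primitive the layer-product selection algorithm depends
# on: both LOH construction (iterative layer peeling) and the final
# k-selection over candidate sums reduce to partition_by_rank().

#' Select the k-th smallest value in linear time
#'
#' Returns the value that would occupy position `k` (1-based) if `values`
#' were sorted ascending, without sorting. Uses the classic groups-of-five
#' median-of-medians pivot, which guarantees worst-case linear time; inputs
#' shorter than 10 are sorted directly. Duplicates are treated as a multiset,
#' so e.g. rank 2 of `c(7, 7, 1)` is 7.
#'
#' @param values numeric vector; must be non-empty and free of `NA`.
#' @param k integer rank, `1 <= k <= length(values)`. Rank 1 is the minimum,
#'   rank `length(values)` the maximum.
#' @return A single value: the k-th smallest element of `values`.
#' @examples
#' select_nth(c(8, 1, 6, 4, 5, 3, 2), 7)  # 8, the maximum
#' select_nth(c(8, 1, 6, 4, 5, 3, 2), 1)  # 1, the minimum
#' @seealso [partition_by_rank()] for splitting around a rank.
#' @export
select_nth <- function(values, k) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector")
  }
  if (anyNA(values)) stop("`values` must not contain NA")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != as.integer(k)) {
    stop("`k` must be a single integer")
  }
  k <- as.integer(k)
  if (k < 1L || k > length(values)) {
    stop(sprintf("rank k = %d out of range [1, %d]", k, length(values)))
  }
  .mom_select(values, k)
}

#' Partition a vector around a rank
#'
#' Splits `values` into a `left` part holding the `left_count` smallest
#' elements (as a multiset) and a `right` part holding the rest, with
#' `max(left) <= min(right)`. Elements equal to the threshold value (the
#' `left_count`-th smallest) are distributed between the two sides so that
#' the counts come out exact; within each side the order is arbitrary.
#' The input is not modified.
#'
#' @param values numeric vector, no `NA`.
#' @param left_count integer, `0 <= left_count <= length(values)`; the number
#'   of elements to place on the left. `left_count = 0` returns an empty left
#'   side and the input on the right.
#' @return A list with components `left` and `right`; their concatenation is
#'   a permutation of `values`.
#' @examples
#' p <- partition_by_rank(c(8, 1, 6, 4, 5, 3, 2), 3)
#' sort(p$left)   # 1 2 3
#' sort(p$right)  # 4 5 6 8
#' @export
partition_by_rank <- function(values, left_count) {
  if (!is.numeric(values)) stop("`values` must be a numeric vector")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (!is.numeric(left_count) || length(left_count) != 1L || is.na(left_count) ||
      left_count != as.integer(left_count)) {
    stop("`left_count` must be a single integer")
  }
  left_count <- as.integer(left_count)
  n <- length(values)
  if (left_count < 0L || left_count > n) {
    stop(sprintf("`left_count` = %d out of range [0, %d]", left_count, n))
  }
  if (left_count == 0L) return(list(left = values[0], right = values))
  if (left_count == n) return(list(left = values, right = values[0]))
  thr <- .mom_select(values, left_count)
  below <- values < thr
  above <- values > thr
  ties <- values[!below & !above]
  n_tie_left <- left_count - sum(below)
  list(
    left  = c(values[below], ties[seq_len(n_tie_left)]),
    right = c(values[above], ties[seq_len(length(ties) - n_tie_left) + n_tie_left])
  )
}

# Recursive median-of-medians selection, 1-based rank. Short inputs are
# sorted; otherwise the pivot is the (lower) median of group-of-5 medians,
# which bounds both recursion branches away from n.
.mom_select <- function(x, k) {
  n <- length(x)
  if (n < 10L) return(sort.int(x)[k])
  piv <- .mom_pivot(x)
  lo <- x[x < piv]
  nlo <- length(lo)
  if (k <= nlo) return(.mom_select(lo, k))
  neq <- n - nlo - sum(x > piv)
  if (k <= nlo + neq) return(piv)
  .mom_select(x[x > piv], k - nlo - neq)
}

# Median of contiguous groups of five (remainder group by direct sort),
# then recursive selection of the lower median of those medians.
.mom_pivot <- function(x) {
  n <- length(x)
  g <- n %/% 5L
  m <- 5L * g
  meds <- .median5(
    x[seq.int(1L, m, 5L)], x[seq.int(2L, m, 5L)], x[seq.int(3L, m, 5L)],
    x[seq.int(4L, m, 5L)], x[seq.int(5L, m, 5L)]
  )
  if (n > m) {
    r <- n - m
    meds <- c(meds, sort.int(x[(m + 1L):n])[(r + 1L) %/% 2L])
  }
  .mom_select(meds, (length(meds) + 1L) %/% 2L)
}

# Element-wise median of five equal-length vectors via the optimal
# 9-comparator sorting network; the middle wire holds the median.
.median5 <- function(a, b, c, d, e) {
  t <- pmin(a, b); b <- pmax(a, b); a <- t
  t <- pmin(d, e); e <- pmax(d, e); d <- t
  t <- pmin(c, e); e <- pmax(c, e); c <- t
  t <- pmin(c, d); d <- pmax(c, d); c <- t
  t <- pmin(a, d); d <- pmax(a, d); a <- t
  t <- pmin(a, c); c <- pmax(a, c); a <- t
  t <- pmin(b, e); e <- pmax(b, e); b <- t
  t <- pmin(b, d); d <- pmax(b, d); b <- t
  pmax(b, c)
}

# partition_by_rank that also carries original positions through the split;
# used by lohify() so layers remember where their values came from.
.partition_with_index <- function(values, idx, left_count) {
  n <- length(values)
  if (left_count == 0L) {
    return(list(left = values[0], left_idx = idx[0], right = values, right_idx = idx))
  }
  if (left_count == n) {
    return(list(left = values, left_idx = idx, right = values[0], right_idx = idx[0]))
  }
  thr <- .mom_select(values, left_count)
  below <- which(values < thr)
  above <- which(values > thr)
  tie <- which(values == thr)
  need <- left_count - length(below)
  left_sel <- c(below, tie[seq_len(need)])
  right_sel <- c(above, tie[seq_len(length(tie) - need) + need])
  list(
    left = values[left_sel], left_idx = idx[left_sel],
    right = values[right_sel], right_idx = idx[right_sel]
  )
}
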