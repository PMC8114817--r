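# Reference implementations for top-k on X + Y. All three materialize or
# enumerate far more than the LOH method needs; they exist as correctness
# oracles and benchmark comparators.

#' Top-k on X + Y by sorting all sums
#'
#' Materializes all `length(x) * length(y)` pairwise sums, sorts them, and
#' returns the first k — the O(n^2 log n) naive reference.
#'
#' @inheritParams select_topk
#' @param k integer, `1 <= k <= length(x) * length(y)`.
#' @return Numeric vector of the k smallest sums, ascending.
#' @export
topk_sort <- function(x, y, k) {
  .check_xy(x, y)
  .check_k(k, length(x), length(y))
  sort(as.vector(outer(x, y, `+`)))[seq_len(k)]
}

#' Top-k on X + Y by k-selection over all sums
#'
#' Materializes all pairwise sums and applies one linear-time k-selection —
#' the O(n^2) naive reference. Output order is unspecified.
#'
#' @inheritParams topk_sort
#' @return Numeric vector of the k smallest sums (unsorted).
#' @export
topk_select <- function(x, y, k) {
  .check_xy(x, y)
  .check_k(k, length(x), length(y))
  partition_by_rank(as.vector(outer(x, y, `+`)), as.integer(k))$left
}

#' Top-k on X + Y by combinatoric heap enumeration
#'
#' Lazily enumerates pair sums in ascending order: `x` and `y` are first
#' arranged as implicit binary min-heaps (so `x[i] <= x[2i], x[2i+1]`), and
#' a priority queue seeded with `(x[1] + y[1], 1, 1)` is popped k times.
#' Popping `(v, i, j)` proposes its successor index pairs — for `j = 1`:
#' `(2i, 1)`, `(2i+1, 1)`, `(i, 2)`, `(i, 3)`; for `j > 1`: `(i, 2j)`,
#' `(i, 2j+1)` — a row-major scheme that reaches every pair exactly once,
#' so no duplicate bookkeeping is needed (out-of-range children are
#' skipped). The k popped values come out exactly sorted. This mirrors the
#' proposal structure of soft-heap-based selection, with an exact binary
#' queue in place of the approximate heap.
#'
#' @inheritParams topk_sort
#' @param debug if `TRUE`, also verify at runtime that no index pair is
#'   proposed twice, and attach the number of queue insertions as attribute
#'   `"insertions"`.
#' @return Numeric vector of the k smallest sums, ascending.
#' @export
topk_comb_heap <- function(x, y, k, debug = FALSE) {
  .check_xy(x, y)
  .check_k(k, length(x), length(y))
  k <- as.integer(k)
  hx <- .binheapify(x)
  hy <- .binheapify(y)
  nx <- length(hx)
  ny <- length(hy)

  pq <- .heap_new(3L)
  inserted <- if (debug) new.env(parent = emptyenv(), hash = TRUE) else NULL
  n_insert <- 0L
  push_pair <- function(i, j) {
    if (i > nx || j > ny) return(invisible(NULL))
    if (debug) {
      id <- paste(i, j, sep = "_")
      if (!is.null(inserted[[id]])) {
        stop(sprintf("index pair (%d, %d) proposed twice", i, j))
      }
      inserted[[id]] <- TRUE
    }
    n_insert <<- n_insert + 1L
    .heap_push(pq, c(hx[i] + hy[j], i, j))
    invisible(NULL)
  }
  push_pair(1L, 1L)

  out <- numeric(k)
  for (m in seq_len(k)) {
    key <- .heap_pop(pq)
    out[m] <- key[1]
    i <- as.integer(key[2]); j <- as.integer(key[3])
    if (j == 1L) {
      push_pair(2L * i, 1L)
      push_pair(2L * i + 1L, 1L)
      push_pair(i, 2L)
      push_pair(i, 3L)
    } else {
      push_pair(i, 2L * j)
      push_pair(i, 2L * j + 1L)
    }
  }
  if (debug) attr(out, "insertions") <- n_insert
  out
}

# Arrange a vector as an implicit binary min-heap (1-based: parent i,
# children 2i and 2i+1) by iterative sift-down, in O(n).
.binheapify <- function(x) {
  n <- length(x)
  for (start in rev(seq_len(n %/% 2L))) {
    i <- start
    repeat {
      l <- 2L * i; r <- l + 1L
      smallest <- i
      if (l <= n && x[l] < x[smallest]) smallest <- l
      if (r <= n && x[r] < x[smallest]) smallest <- r
      if (smallest == i) break
      tmp <- x[smallest]; x[smallest] <- x[i]; x[i] <- tmp
      i <- smallest
    }
  }
  x
}
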