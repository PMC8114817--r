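# Top-k selection on the Cartesian sum X + Y via layer products.
#
# After LOHifying X and Y (phase 0), the algorithm never materializes the
# n_x * n_y sum matrix. It works on "layer products" X^(u) + Y^(v), each
# summarized by two corner keys: the minimum corner (smallest possible sum
# in the product) and the maximum corner (largest). Corner keys are totally
# ordered tuples (value, u, v, flag) with flag MIN = 0 < MAX = 1, so even a
# product whose values are all equal has min corner < max corner. A small
# priority queue sweeps the corners in ascending order (phase 1) until the
# area of the products whose max corner has been popped reaches k; the
# products whose min corner was reached but whose max corner is still
# pending are swept up afterwards (phase 2). Together those products are
# guaranteed to contain the k smallest sums, and their total area is O(k),
# so one linear-time k-selection over the inflated candidates (phase 3)
# finishes the job. Total work: O(n + k).

.FLAG_MIN <- 0
.FLAG_MAX <- 1

#' Corner keys of a layer product
#'
#' The corner keys of layer product `X^(u) + Y^(v)` summarize its smallest
#' and largest possible sums using only the cached layer extrema — the
#' product itself is never materialized. Keys are totally ordered
#' lexicographically on `(value, u, v, flag)` with the MIN flag (0) sorting
#' before the MAX flag (1), which breaks ties between products with
#' identical values.
#'
#' @param loh_x,loh_y layer-ordered heaps from [lohify()].
#' @param u,v layer indices into `loh_x` and `loh_y` (1-based).
#' @return A list with components `min` and `max`, each a named numeric
#'   vector `c(value, u, v, flag)`.
#' @examples
#' hx <- lohify(c(8, 1, 6, 4, 5, 3, 2))
#' hy <- lohify(c(10, 0, 20))
#' corner_keys(hx, hy, 1, 1)$min[["value"]]  # 1 + 0
#' @export
corner_keys <- function(loh_x, loh_y, u, v) {
  stopifnot(inherits(loh_x, "loh"), inherits(loh_y, "loh"))
  if (u < 1L || u > length(loh_x$layers) || v < 1L || v > length(loh_y$layers)) {
    stop(sprintf("layer pair (%d, %d) out of bounds", u, v))
  }
  list(
    min = c(value = loh_x$mins[u] + loh_y$mins[v], u = u, v = v, flag = .FLAG_MIN),
    max = c(value = loh_x$maxs[u] + loh_y$maxs[v], u = u, v = v, flag = .FLAG_MAX)
  )
}

# Internal corner key with the product area appended (not compared).
.corner_key <- function(loh_x, loh_y, u, v, flag) {
  area <- length(loh_x$layers[[u]]) * length(loh_y$layers[[v]])
  if (flag == .FLAG_MIN) {
    c(loh_x$mins[u] + loh_y$mins[v], u, v, .FLAG_MIN, area)
  } else {
    c(loh_x$maxs[u] + loh_y$maxs[v], u, v, .FLAG_MAX, area)
  }
}

#' Phase-1 corner sweep
#'
#' Sweeps the corner keys of layer products in ascending order with a
#' binary min-heap seeded with the (1, 1) min corner. Popping a min corner
#' at `(u, v)` inserts the min corners of `(u + 1, v)` and `(u, v + 1)` and
#' the max corner of `(u, v)` (bounds permitting; a membership set prevents
#' duplicates). Popping a max corner commits the product: its index joins
#' the list `q` and its area accumulates into `s`. The sweep halts as soon
#' as `s >= k`; the value of the final popped key is the threshold `tau`,
#' an upper bound on the k-th smallest sum.
#'
#' @param loh_x,loh_y layer-ordered heaps of the two input vectors.
#' @param k integer, `1 <= k <= n_x * n_y`.
#' @param record_pops if `TRUE`, every popped key is recorded in the trace
#'   (used to check the ascending-pop and pop-precedence properties).
#' @return A list with `trace` (class `"sum_selection_trace"`: `q` as a
#'   two-column matrix of committed layer pairs, `area` per pair, `phase`
#'   markers, `s`, `s_prime = NA` until phase 2, `tau`, `pop_count`, and
#'   optionally `pops`) and `frontier` (matrix of keys still pending in the
#'   heap, columns value/u/v/flag/area).
#' @seealso [phase2_collect()], [select_topk()]
#' @export
phase1_sweep <- function(loh_x, loh_y, k, record_pops = FALSE) {
  stopifnot(inherits(loh_x, "loh"), inherits(loh_y, "loh"))
  .check_k(k, loh_x$n, loh_y$n, allow_zero = FALSE)
  k <- as.integer(k)
  Lx <- length(loh_x$layers)
  Ly <- length(loh_y$layers)

  h <- .heap_new(5L, ncmp = 4L)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  push_if <- function(u, v, flag) {
    if (u > Lx || v > Ly) return(invisible(NULL))
    id <- paste(u, v, flag, sep = "_")
    if (!is.null(seen[[id]])) return(invisible(NULL))
    seen[[id]] <- TRUE
    .heap_push(h, .corner_key(loh_x, loh_y, u, v, flag))
    invisible(NULL)
  }
  push_if(1L, 1L, .FLAG_MIN)

  q_u <- integer(0); q_v <- integer(0); q_area <- numeric(0)
  s <- 0
  tau <- NA_real_
  pop_count <- 0L
  pops <- if (record_pops) list() else NULL

  repeat {
    key <- .heap_pop(h)
    pop_count <- pop_count + 1L
    if (record_pops) pops[[pop_count]] <- key[1:4]
    u <- as.integer(key[2]); v <- as.integer(key[3])
    rm(list = paste(u, v, key[4], sep = "_"), envir = seen)
    if (key[4] == .FLAG_MIN) {
      push_if(u + 1L, v, .FLAG_MIN)
      push_if(u, v + 1L, .FLAG_MIN)
      push_if(u, v, .FLAG_MAX)
    } else {
      q_u <- c(q_u, u); q_v <- c(q_v, v); q_area <- c(q_area, key[5])
      s <- s + key[5]
      if (s >= k) {
        tau <- key[1]
        break
      }
    }
  }

  trace <- structure(
    list(
      q = cbind(u = q_u, v = q_v),
      area = q_area,
      phase = rep(1L, length(q_u)),
      s = s,
      s_prime = NA_real_,
      tau = tau,
      k = k,
      pop_count = pop_count,
      pops = if (record_pops) do.call(rbind, pops) else NULL
    ),
    class = "sum_selection_trace"
  )
  list(trace = trace, frontier = .heap_contents(h))
}

#' Phase-2 frontier collection
#'
#' Every max corner still pending in the frontier when phase 1 halts marks
#' a layer product whose min corner was reached (so it may contain sums
#' below the threshold `tau`) but whose area was never committed. Phase 2
#' appends each such product to `q` and accumulates its area into
#' `s_prime`; pending min corners are ignored. After this step the products
#' in `q` are guaranteed to contain the k smallest sums.
#'
#' @param trace a `"sum_selection_trace"` from [phase1_sweep()].
#' @param frontier the pending-key matrix from [phase1_sweep()].
#' @return The updated trace with phase-2 entries appended and `s_prime`
#'   set.
#' @export
phase2_collect <- function(trace, frontier) {
  stopifnot(inherits(trace, "sum_selection_trace"))
  pend_max <- frontier[frontier[, 4] == .FLAG_MAX, , drop = FALSE]
  n2 <- nrow(pend_max)
  trace$q <- rbind(trace$q, cbind(u = as.integer(pend_max[, 2]),
                                  v = as.integer(pend_max[, 3])))
  trace$area <- c(trace$area, pend_max[, 5])
  trace$phase <- c(trace$phase, rep(2L, n2))
  trace$s_prime <- if (n2 > 0L) sum(pend_max[, 5]) else 0
  trace
}

#' Inflate the candidate sums of committed layer products
#'
#' Materializes `x + y` for every pair in every layer product listed in
#' `q`. This is the only step whose cost depends on k: the listed products
#' have total area `s + s_prime`, which is O(k).
#'
#' @param loh_x,loh_y the layer-ordered heaps the trace was computed from.
#' @param q a two-column matrix of layer pairs (e.g. `trace$q`), or a
#'   `"sum_selection_trace"`.
#' @return Numeric vector of candidate sums, length `sum of product areas`.
#' @export
inflate_candidates <- function(loh_x, loh_y, q) {
  stopifnot(inherits(loh_x, "loh"), inherits(loh_y, "loh"))
  if (inherits(q, "sum_selection_trace")) q <- q$q
  if (nrow(q) == 0L) return(numeric(0))
  parts <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    parts[[i]] <- as.vector(outer(loh_x$layers[[q[i, 1]]], loh_y$layers[[q[i, 2]]], `+`))
  }
  unlist(parts, use.names = FALSE)
}

#' Select the k smallest values of the Cartesian sum X + Y
#'
#' Returns the k smallest values of the multiset `{x_i + y_j}` in
#' O(n + k) time, without materializing the full sum matrix. The method
#' LOHifies both inputs (phase 0), sweeps layer-product corner keys in
#' ascending order until the committed area reaches k (phase 1), collects
#' the still-open products from the frontier (phase 2), and runs one
#' linear-time k-selection over the inflated candidates (phase 3). Ties at
#' the k-th value are resolved by count: exactly `k` values are returned,
#' with duplicates of the threshold filling the tail.
#'
#' @param x,y non-empty numeric vectors, no `NA`.
#' @param k integer, `0 <= k <= length(x) * length(y)`; `k = 0` returns an
#'   empty result.
#' @param alpha layer growth rank for the LOHs, `> 1`; default 2.
#' @param sort_values if `TRUE` the returned values are sorted ascending;
#'   by default they come back in unspecified (selection) order.
#' @param record_pops if `TRUE` the trace keeps the full popped-key
#'   sequence (diagnostic; see [phase1_sweep()]).
#' @return An object of class `"sum_selection"`: a list with `values`
#'   (numeric, length `k`), `k`, `alpha`, and `trace` (see
#'   [phase1_sweep()]; `trace$s + trace$s_prime` is the candidate count and
#'   `trace$tau` the phase-1 threshold).
#' @examples
#' sel <- select_topk(c(1, 2), c(10, 20), k = 2)
#' sort(sel$values)  # 11 12
#' @seealso [select_topk_sorted_corners()] for the sorted-corner variant,
#'   [select_topk_compressed()] to stop after phase 2, [topk_sort()] for
#'   the quadratic reference.
#' @export
select_topk <- function(x, y, k, alpha = 2, sort_values = FALSE, record_pops = FALSE) {
  .check_xy(x, y)
  .check_alpha(alpha)
  .check_k(k, length(x), length(y), allow_zero = TRUE)
  k <- as.integer(k)
  if (k == 0L) {
    return(structure(list(values = numeric(0), k = 0L, alpha = alpha, trace = NULL),
                     class = "sum_selection"))
  }
  loh_x <- lohify(x, alpha)
  loh_y <- lohify(y, alpha)
  .select_from_lohs(loh_x, loh_y, k, alpha, sort_values, record_pops)
}

# Phases 1-3 on pre-built LOHs; shared by select_topk() and the overshoot
# benchmark (which reuses one LOHification across several k).
.select_from_lohs <- function(loh_x, loh_y, k, alpha, sort_values = FALSE,
                              record_pops = FALSE) {
  p1 <- phase1_sweep(loh_x, loh_y, k, record_pops = record_pops)
  trace <- phase2_collect(p1$trace, p1$frontier)
  candidates <- inflate_candidates(loh_x, loh_y, trace$q)
  values <- partition_by_rank(candidates, k)$left
  if (sort_values) values <- sort(values)
  structure(list(values = values, k = k, alpha = alpha, trace = trace),
            class = "sum_selection")
}

#' Top-k on X + Y by fully sorting the corner keys
#'
#' A simplified variant of [select_topk()] with the same asymptotic
#' runtime: all `2 * L_x * L_y` corner keys are sorted ascending (still
#' o(n) keys) and scanned once. A min-corner visit inflates that product
#' into the candidate pool; a max-corner visit commits its area. The scan
#' stops when the committed area reaches k, and a linear-time k-selection
#' finishes. Slower in practice when `k << n^2` because candidates are
#' inflated eagerly, but considerably simpler.
#'
#' @inheritParams select_topk
#' @return A `"sum_selection"` object; `values` agrees with
#'   [select_topk()] as a multiset.
#' @export
select_topk_sorted_corners <- function(x, y, k, alpha = 2, sort_values = FALSE) {
  .check_xy(x, y)
  .check_alpha(alpha)
  .check_k(k, length(x), length(y), allow_zero = TRUE)
  k <- as.integer(k)
  if (k == 0L) {
    return(structure(list(values = numeric(0), k = 0L, alpha = alpha, trace = NULL),
                     class = "sum_selection"))
  }
  loh_x <- lohify(x, alpha)
  loh_y <- lohify(y, alpha)
  Lx <- length(loh_x$layers)
  Ly <- length(loh_y$layers)

  grid <- expand.grid(u = seq_len(Lx), v = seq_len(Ly))
  corners <- rbind(
    cbind(loh_x$mins[grid$u] + loh_y$mins[grid$v], grid$u, grid$v, .FLAG_MIN),
    cbind(loh_x$maxs[grid$u] + loh_y$maxs[grid$v], grid$u, grid$v, .FLAG_MAX)
  )
  corners <- corners[order(corners[, 1], corners[, 2], corners[, 3], corners[, 4]), ,
                     drop = FALSE]

  candidates <- vector("list", nrow(corners))
  q_u <- integer(0); q_v <- integer(0); q_area <- numeric(0); q_phase <- integer(0)
  committed <- 0
  min_u <- integer(0); min_v <- integer(0)  # products whose min corner was visited
  i <- 0L
  tau <- NA_real_
  while (committed < k) {
    i <- i + 1L
    u <- corners[i, 2]; v <- corners[i, 3]
    if (corners[i, 4] == .FLAG_MAX) {
      area <- length(loh_x$layers[[u]]) * length(loh_y$layers[[v]])
      committed <- committed + area
      q_u <- c(q_u, u); q_v <- c(q_v, v); q_area <- c(q_area, area)
      q_phase <- c(q_phase, 1L)
      tau <- corners[i, 1]
    } else {
      candidates[[i]] <- as.vector(outer(loh_x$layers[[u]], loh_y$layers[[v]], `+`))
      min_u <- c(min_u, u); min_v <- c(min_v, v)
    }
  }
  # products opened (min corner seen) but never committed mirror phase 2
  open <- !(paste(min_u, min_v) %in% paste(q_u, q_v))
  open_area <- lengths(loh_x$layers)[min_u[open]] * lengths(loh_y$layers)[min_v[open]]
  trace <- structure(
    list(
      q = cbind(u = c(q_u, min_u[open]), v = c(q_v, min_v[open])),
      area = c(q_area, open_area),
      phase = c(q_phase, rep(2L, sum(open))),
      s = committed,
      s_prime = sum(open_area),
      tau = tau,
      k = k,
      pop_count = i,
      pops = NULL
    ),
    class = "sum_selection_trace"
  )
  values <- partition_by_rank(unlist(candidates, use.names = FALSE), k)$left
  if (sort_values) values <- sort(values)
  structure(list(values = values, k = k, alpha = alpha, trace = trace),
            class = "sum_selection")
}

#' Top-k on X + Y in compressed layer-product form
#'
#' Runs phases 0-2 only and returns the committed layer products without
#' inflating them. The union of the listed products is guaranteed to
#' contain the k smallest sums, and phases 0-2 cost O(n) regardless of k —
#' useful when a factored representation of the answer suffices. Inflate
#' with [inflate_candidates()] and k-select to recover the explicit values.
#'
#' @inheritParams select_topk
#' @return An object of class `"sum_selection_compressed"`: a list with
#'   `q` (two-column matrix of layer pairs), `trace`, `loh_x`, `loh_y`,
#'   `k`, and `alpha`.
#' @examples
#' cs <- select_topk_compressed(c(1, 2, 9), c(0, 5), k = 3)
#' sort(partition_by_rank(inflate_candidates(cs$loh_x, cs$loh_y, cs$q), 3)$left)
#' @export
select_topk_compressed <- function(x, y, k, alpha = 2) {
  .check_xy(x, y)
  .check_alpha(alpha)
  .check_k(k, length(x), length(y), allow_zero = TRUE)
  k <- as.integer(k)
  loh_x <- lohify(x, alpha)
  loh_y <- lohify(y, alpha)
  if (k == 0L) {
    return(structure(
      list(q = cbind(u = integer(0), v = integer(0)), trace = NULL,
           loh_x = loh_x, loh_y = loh_y, k = 0L, alpha = alpha),
      class = "sum_selection_compressed"
    ))
  }
  p1 <- phase1_sweep(loh_x, loh_y, k)
  trace <- phase2_collect(p1$trace, p1$frontier)
  structure(
    list(q = trace$q, trace = trace, loh_x = loh_x, loh_y = loh_y,
         k = k, alpha = alpha),
    class = "sum_selection_compressed"
  )
}

#' @export
print.sum_selection <- function(x, ...) {
  cat(sprintf("Top-%d selection on X + Y (alpha = %g)\n", x$k, x$alpha))
  if (!is.null(x$trace)) {
    cat(sprintf(
      "phase 1: s = %g over %d products, tau = %g; phase 2: s' = %g; overshoot (s + s')/k = %.3f\n",
      x$trace$s, sum(x$trace$phase == 1L), x$trace$tau, x$trace$s_prime,
      (x$trace$s + x$trace$s_prime) / x$k
    ))
  }
  cat("values:", paste(utils::head(sort(x$values), 20L), collapse = " "),
      if (x$k > 20L) "...\n" else "\n")
  invisible(x)
}

#' @export
print.sum_selection_compressed <- function(x, ...) {
  cat(sprintf(
    "Compressed top-%d selection: %d layer products covering %g candidate sums\n",
    x$k, nrow(x$q), if (is.null(x$trace)) 0 else x$trace$s + x$trace$s_prime
  ))
  invisible(x)
}

.check_xy <- function(x, y) {
  if (!is.numeric(x) || length(x) == 0L || !is.numeric(y) || length(y) == 0L) {
    stop("`x` and `y` must be non-empty numeric vectors")
  }
  if (anyNA(x) || anyNA(y)) stop("`x` and `y` must not contain NA")
  invisible(NULL)
}

.check_k <- function(k, nx, ny, allow_zero = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != as.integer(k)) {
    stop("`k` must be a single integer")
  }
  lo <- if (allow_zero) 0L else 1L
  if (k < lo || k > nx * ny) {
    stop(sprintf("`k` = %d out of range [%d, %d]", as.integer(k), lo, nx * ny))
  }
  invisible(NULL)
}
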