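# Layer-ordered heaps: partitions of a vector into ascending layers whose
# sizes grow geometrically at rank alpha. Construction peels the largest
# remaining layer with linear-time rank selection, so the whole build is
# O(n) for any fixed alpha > 1.

#' Layer sizes for a layer-ordered heap
#'
#' Computes the ascending layer-size schedule for `n` elements at rank
#' `alpha`: layer u has scheduled size `ceiling(alpha^(u-1))`, and the final
#' layer is truncated so the sizes sum to `n`. For `alpha = 2` this is the
#' doubling schedule 1, 2, 4, 8, ..., remainder.
#'
#' @param n non-negative integer, total element count.
#' @param alpha layer growth rank, a single number `> 1`. `alpha = 1` would
#'   make every layer a singleton (i.e. a full sort) and is rejected.
#' @return Integer vector of layer sizes summing to `n`; `integer(0)` when
#'   `n = 0`.
#' @examples
#' layer_size_schedule(7, 2)   # 1 2 4
#' layer_size_schedule(12, 2)  # 1 2 4 5
#' @export
layer_size_schedule <- function(n, alpha = 2) {
  .check_alpha(alpha)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != as.integer(n) || n < 0) {
    stop("`n` must be a single non-negative integer")
  }
  n <- as.integer(n)
  if (n == 0L) return(integer(0))
  sizes <- integer(0)
  total <- 0L
  u <- 0
  while (total < n) {
    s <- min(as.integer(ceiling(alpha^u)), n - total)
    sizes <- c(sizes, s)
    total <- total + s
    u <- u + 1
  }
  sizes
}

#' Construct a layer-ordered heap
#'
#' Partitions `values` into ascending layers: every value in layer u is
#' `<=` every value in layer u+1, while values *within* a layer stay
#' unordered. Layer sizes follow [layer_size_schedule()]. Construction
#' iteratively selects and removes the largest remaining layer with
#' [partition_by_rank()], which keeps the total work linear in
#' `length(values)` for fixed `alpha`.
#'
#' The returned object also records, for each layer, the original positions
#' of its values in the input vector, so callers can trace selected sums
#' back to input elements.
#'
#' @param values numeric vector (possibly empty), no `NA`.
#' @param alpha layer growth rank, `> 1`; defaults to 2 (doubling layers).
#' @return An object of class `"loh"`: a list with `layers` (list of numeric
#'   vectors, ascending layer order), `indices` (list of integer vectors of
#'   original positions, parallel to `layers`), `mins`/`maxs` (cached
#'   per-layer extrema), `alpha`, and `n`.
#' @examples
#' h <- lohify(c(8, 1, 6, 4, 5, 3, 2), alpha = 2)
#' lapply(h$layers, sort)  # {1} <= {2,3} <= {4,5,6,8}
#' @export
lohify <- function(values, alpha = 2) {
  .check_alpha(alpha)
  if (!is.numeric(values)) stop("`values` must be a numeric vector")
  if (anyNA(values)) stop("`values` must not contain NA")
  n <- length(values)
  sizes <- layer_size_schedule(n, alpha)
  L <- length(sizes)
  layers <- vector("list", L)
  indices <- vector("list", L)
  cur <- values
  idx <- seq_len(n)
  for (u in rev(seq_len(L))) {
    sp <- .partition_with_index(cur, idx, length(cur) - sizes[u])
    layers[[u]] <- sp$right
    indices[[u]] <- sp$right_idx
    cur <- sp$left
    idx <- sp$left_idx
  }
  structure(
    list(
      layers = layers,
      indices = indices,
      mins = vapply(layers, min, numeric(1)),
      maxs = vapply(layers, max, numeric(1)),
      alpha = alpha,
      n = n
    ),
    class = "loh"
  )
}

#' Per-layer extrema of a layer-ordered heap
#'
#' @param loh an object created by [lohify()].
#' @param u layer index, `1 <= u <= length(loh)`.
#' @return Named numeric vector `c(min = , max = )` with the cached extrema
#'   of layer `u`.
#' @examples
#' layer_extrema(lohify(c(8, 1, 6, 4, 5, 3, 2)), 3)  # min 4, max 8
#' @export
layer_extrema <- function(loh, u) {
  stopifnot(inherits(loh, "loh"))
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u != as.integer(u) ||
      u < 1L || u > length(loh$layers)) {
    stop(sprintf("layer index u out of range [1, %d]", length(loh$layers)))
  }
  c(min = loh$mins[u], max = loh$maxs[u])
}

#' Check the invariants of a layer-ordered heap
#'
#' Verifies the layer-ordering property (each layer's maximum no larger than
#' the next layer's minimum), that the cached extrema match the stored
#' layers, that realized layer sizes follow [layer_size_schedule()], and
#' that the element count is consistent.
#'
#' @param loh an object of class `"loh"` (possibly hand-built, e.g. to test
#'   a suspect structure).
#' @return A list with `ok` (logical), `failures` (character vector of
#'   human-readable violation descriptions, empty when `ok`), and
#'   `first_bad_pair` (`c(u, u + 1)` for the first adjacent layer pair that
#'   violates the ordering, or `NULL`).
#' @examples
#' verify_loh(lohify(rnorm(100)))$ok  # TRUE
#' @export
verify_loh <- function(loh) {
  stopifnot(inherits(loh, "loh"))
  failures <- character(0)
  first_bad_pair <- NULL
  L <- length(loh$layers)
  for (u in seq_len(max(0L, L - 1L))) {
    if (max(loh$layers[[u]]) > min(loh$layers[[u + 1L]])) {
      failures <- c(failures, sprintf(
        "layer ordering violated between layers %d and %d: max %g > min %g",
        u, u + 1L, max(loh$layers[[u]]), min(loh$layers[[u + 1L]])
      ))
      if (is.null(first_bad_pair)) first_bad_pair <- c(u, u + 1L)
    }
  }
  for (u in seq_len(L)) {
    if (loh$mins[u] != min(loh$layers[[u]]) || loh$maxs[u] != max(loh$layers[[u]])) {
      failures <- c(failures, sprintf("cached extrema of layer %d are stale", u))
    }
  }
  sizes <- vapply(loh$layers, length, integer(1))
  if (sum(sizes) != loh$n) {
    failures <- c(failures, sprintf(
      "element count mismatch: layers hold %d values, n = %d", sum(sizes), loh$n
    ))
  }
  sched <- layer_size_schedule(loh$n, loh$alpha)
  if (length(sched) != L || any(sizes != sched)) {
    failures <- c(failures, "realized layer sizes do not match the schedule")
  }
  list(ok = length(failures) == 0L, failures = failures, first_bad_pair = first_bad_pair)
}

#' @export
length.loh <- function(x) length(x$layers)

#' @export
print.loh <- function(x, ...) {
  cat(sprintf(
    "Layer-ordered heap: %d values in %d layers (alpha = %g)\n",
    x$n, length(x$layers), x$alpha
  ))
  sizes <- vapply(x$layers, length, integer(1))
  cat("layer sizes:", paste(sizes, collapse = " "), "\n")
  if (length(x$layers) > 0L) {
    cat("layer ranges:",
        paste(sprintf("[%g, %g]", x$mins, x$maxs), collapse = " "), "\n")
  }
  invisible(x)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 1) {
    stop("`alpha` must be a single number > 1 (alpha = 1 degenerates to sorting)")
  }
  invisible(alpha)
}
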