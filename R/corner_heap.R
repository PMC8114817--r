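# Small binary min-heap over fixed-width numeric keys, compared
# lexicographically on their first `ncmp` columns. The frontier of layer
# products holds at most O(log^2 n) keys, so a plain R implementation is
# ample; the heap lives in an environment for in-place updates.

.heap_new <- function(ncol, ncmp = ncol) {
  h <- new.env(parent = emptyenv())
  h$keys <- matrix(0, nrow = 16L, ncol = ncol)
  h$n <- 0L
  h$ncmp <- ncmp
  h
}

.key_lt <- function(a, b, ncmp) {
  for (i in seq_len(ncmp)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

.heap_push <- function(h, key) {
  if (h$n == nrow(h$keys)) {
    h$keys <- rbind(h$keys, matrix(0, nrow = nrow(h$keys), ncol = ncol(h$keys)))
  }
  i <- h$n + 1L
  h$keys[i, ] <- key
  h$n <- i
  while (i > 1L) {
    p <- i %/% 2L
    if (.key_lt(h$keys[i, ], h$keys[p, ], h$ncmp)) {
      tmp <- h$keys[p, ]
      h$keys[p, ] <- h$keys[i, ]
      h$keys[i, ] <- tmp
      i <- p
    } else break
  }
  invisible(h)
}

.heap_pop <- function(h) {
  stopifnot(h$n > 0L)
  top <- h$keys[1L, ]
  h$keys[1L, ] <- h$keys[h$n, ]
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i
    r <- l + 1L
    smallest <- i
    if (l <= h$n && .key_lt(h$keys[l, ], h$keys[smallest, ], h$ncmp)) smallest <- l
    if (r <= h$n && .key_lt(h$keys[r, ], h$keys[smallest, ], h$ncmp)) smallest <- r
    if (smallest == i) break
    tmp <- h$keys[smallest, ]
    h$keys[smallest, ] <- h$keys[i, ]
    h$keys[i, ] <- tmp
    i <- smallest
  }
  top
}

.heap_contents <- function(h) {
  h$keys[seq_len(h$n), , drop = FALSE]
}
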