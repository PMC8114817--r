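# Helpers for checking the corner-sweep ordering properties from an
# instrumented popped-key trace (columns: value, u, v, flag).

key_leq <- function(a, b) {
  for (i in 1:4) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  TRUE
}

pops_ascending <- function(pops) {
  all(vapply(seq_len(nrow(pops) - 1L),
             function(i) key_leq(pops[i, ], pops[i + 1L, ]), logical(1)))
}

# For every pop of flag `fl` at (u, v), pops of the same flag at (u-1, v)
# and (u, v-1) (when such layers exist) must have occurred earlier.
pops_precedence_ok <- function(pops, fl) {
  rows <- which(pops[, 4] == fl)
  seen <- character(0)
  for (r in rows) {
    u <- pops[r, 2]; v <- pops[r, 3]
    if (u > 1 && !(paste(u - 1, v) %in% seen)) return(FALSE)
    if (v > 1 && !(paste(u, v - 1) %in% seen)) return(FALSE)
    seen <- c(seen, paste(u, v))
  }
  TRUE
}
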