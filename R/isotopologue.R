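# Isotopologue demonstration: ranking the k most abundant combined
# isotope species of two molecular fragments. The abundance of a combined
# species is the product of the fragments' isotopologue probabilities, so
# on the negative-log scale abundances add and "most abundant k pairs"
# becomes exactly top-k selection on a Cartesian sum.

#' Construct an isotope peak list
#'
#' A peak list pairs each isotopologue of a molecular fragment with its
#' monoisotopic-style mass (Da) and probability. Probabilities must be in
#' (0, 1] and may sum to at most 1 (within 1e-6, to absorb rounding in
#' published tables); zero probabilities are rejected because the
#' negative-log transform is undefined for them.
#'
#' @param mass numeric vector of masses in Da, strictly positive.
#' @param probability numeric vector in (0, 1], same length as `mass`.
#' @return A data frame with columns `mass` and `probability`, class
#'   `"isotope_peaks"`.
#' @export
isotope_peaks <- function(mass, probability) {
  if (length(mass) != length(probability) || length(mass) == 0L) {
    stop("`mass` and `probability` must be non-empty and of equal length")
  }
  if (anyNA(mass) || anyNA(probability)) stop("peak list must not contain NA")
  if (any(mass <= 0)) stop("all masses must be strictly positive")
  if (any(probability <= 0) || any(probability > 1)) {
    stop("all probabilities must lie in (0, 1]")
  }
  if (sum(probability) > 1 + 1e-6) {
    stop(sprintf("probabilities sum to %.8f > 1", sum(probability)))
  }
  structure(
    data.frame(mass = as.numeric(mass), probability = as.numeric(probability)),
    class = c("isotope_peaks", "data.frame")
  )
}

#' Read an isotope peak list from a two-column TSV file
#'
#' Each non-comment line must be `mass<TAB>probability`; lines starting
#' with `#` (and blank lines) are skipped. Validation errors name the
#' offending line.
#'
#' @param path path to the TSV file.
#' @return An `"isotope_peaks"` data frame; see [isotope_peaks()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("# carbon", "12\t0.9893", "13.00335\t0.0107"), tf)
#' read_peak_list(tf)
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  mass <- numeric(0)
  prob <- numeric(0)
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals)) {
      stop(sprintf("line %d: expected 'mass<TAB>probability', got %s",
                   i, dQuote(lines[i])))
    }
    if (vals[1] <= 0) stop(sprintf("line %d: mass must be positive", i))
    if (vals[2] <= 0 || vals[2] > 1) {
      stop(sprintf("line %d: probability must lie in (0, 1]", i))
    }
    mass <- c(mass, vals[1])
    prob <- c(prob, vals[2])
  }
  if (length(mass) == 0L) stop("no peaks found in ", path)
  isotope_peaks(mass, prob)
}

#' The k most abundant combined isotopologue pairs of two fragments
#'
#' Combining one isotopologue from each fragment gives a species of mass
#' `mass_A + mass_B` and probability `p_A * p_B`. The k most probable
#' pairs are exactly the k smallest values of the Cartesian sum of the
#' fragments' negative-log probabilities, which this function selects with
#' the compressed layer-product sweep and then maps back to (mass,
#' probability) pairs through the layers' stored input positions. Returned
#' probabilities are recomputed as products of the input probabilities
#' (not exponentiated logs), so they carry no round-trip error.
#'
#' Distinct pairs with equal total mass are *not* merged: aggregating
#' isobaric species is a separate convolution step outside this function's
#' scope.
#'
#' @param a,b `"isotope_peaks"` objects (or data frames with `mass` and
#'   `probability` columns).
#' @param k integer, `1 <= k <= nrow(a) * nrow(b)`.
#' @param alpha layer growth rank for the underlying selection; default 2.
#' @return A data frame with columns `mass` (Da) and `probability`,
#'   descending by probability (ties in arbitrary order), exactly `k`
#'   rows.
#' @examples
#' carbon <- isotope_peaks(c(12, 13.00335), c(0.9893, 0.0107))
#' top_isotopologue_pairs(carbon, carbon, k = 2)
#' @export
top_isotopologue_pairs <- function(a, b, k, alpha = 2) {
  a <- .as_peaks(a)
  b <- .as_peaks(b)
  na <- nrow(a)
  nb <- nrow(b)
  .check_k(k, na, nb, allow_zero = FALSE)
  k <- as.integer(k)

  cs <- select_topk_compressed(-log(a$probability), -log(b$probability), k, alpha)
  # expand committed layer products into original index pairs
  idx_i <- vector("list", nrow(cs$q))
  idx_j <- vector("list", nrow(cs$q))
  for (r in seq_len(nrow(cs$q))) {
    ia <- cs$loh_x$indices[[cs$q[r, 1]]]
    ib <- cs$loh_y$indices[[cs$q[r, 2]]]
    g <- expand.grid(i = ia, j = ib)
    idx_i[[r]] <- g$i
    idx_j[[r]] <- g$j
  }
  i <- unlist(idx_i, use.names = FALSE)
  j <- unlist(idx_j, use.names = FALSE)
  neglog <- -log(a$probability[i]) - log(b$probability[j])
  take <- order(neglog)[seq_len(k)]
  out <- data.frame(
    mass = a$mass[i[take]] + b$mass[j[take]],
    probability = a$probability[i[take]] * b$probability[j[take]]
  )
  out <- out[order(out$probability, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_peaks <- function(p) {
  if (inherits(p, "isotope_peaks")) return(p)
  if (is.data.frame(p) && all(c("mass", "probability") %in% names(p))) {
    return(isotope_peaks(p$mass, p$probability))
  }
  stop("expected an isotope_peaks object or a data frame with mass and probability")
}
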