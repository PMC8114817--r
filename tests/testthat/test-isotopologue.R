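write_peaks <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

test_that("read_peak_list parses TSV peak lists and skips comments", {
  p <- read_peak_list(write_peaks(c("12\t0.989", "13.00335\t0.011")))
  expect_s3_class(p, "isotope_peaks")
  expect_equal(nrow(p), 2)
  expect_equal(p$mass, c(12, 13.00335))
  p1 <- read_peak_list(write_peaks(c("# comment", "", "12\t1.0")))
  expect_equal(nrow(p1), 1)
})

test_that("read_peak_list rejects malformed or invalid lines by number", {
  expect_error(read_peak_list(write_peaks("12\t1.5")), "line 1.*probability")
  expect_error(read_peak_list(write_peaks(c("12\t0.5", "13 0.5"))), "line 2")
  expect_error(read_peak_list(write_peaks("-1\t0.5")), "mass")
  expect_error(read_peak_list(write_peaks("12\t0")), "probability")
  expect_error(read_peak_list(write_peaks("# only comments")), "no peaks")
})

test_that("isotope_peaks enforces the probability budget", {
  expect_error(isotope_peaks(c(12, 13), c(0.9, 0.2)), "sum")
  expect_silent(isotope_peaks(c(12, 13), c(0.9, 0.1)))
})

test_that("single-peak fragments give the single combined species", {
  a <- isotope_peaks(12, 1.0)
  b <- isotope_peaks(1.007825, 1.0)
  top <- top_isotopologue_pairs(a, b, 1)
  expect_equal(top$mass, 13.007825)
  expect_equal(top$probability, 1.0)
})

test_that("the most abundant carbon-carbon pair is the light-light pair", {
  carbon <- isotope_peaks(c(12, 13.00335), c(0.989, 0.011))
  top <- top_isotopologue_pairs(carbon, carbon, 1)
  expect_equal(top$mass, 24)
  expect_equal(top$probability, 0.989^2)
})

test_that("k = |A| * |B| returns every pair, probability-sorted", {
  set.seed(41)
  a <- isotope_peaks(runif(5, 1, 50), prop.table(runif(5)) * 0.99)
  b <- isotope_peaks(runif(4, 1, 50), prop.table(runif(4)) * 0.99)
  top <- top_isotopologue_pairs(a, b, 20)
  expect_equal(nrow(top), 20)
  expect_true(all(diff(top$probability) <= 0))
  brute <- as.vector(outer(a$probability, b$probability))
  expect_equal(sort(top$probability), sort(brute))
  brute_mass <- as.vector(outer(a$mass, b$mass, `+`))
  expect_equal(sort(top$mass), sort(brute_mass))
})

test_that("top-k pairs equal the brute-force largest products on random lists", {
  set.seed(42)
  for (i in 1:40) {
    na <- sample(1:20, 1); nb <- sample(1:20, 1)
    a <- isotope_peaks(runif(na, 1, 100), prop.table(runif(na)) * runif(1, 0.5, 1))
    b <- isotope_peaks(runif(nb, 1, 100), prop.table(runif(nb)) * runif(1, 0.5, 1))
    k <- sample(na * nb, 1)
    top <- top_isotopologue_pairs(a, b, k)
    brute <- sort(as.vector(outer(a$probability, b$probability)), decreasing = TRUE)
    expect_equal(sort(top$probability, decreasing = TRUE), brute[seq_len(k)])
    # conservation: returned mass can never exceed total probability budget
    expect_lte(sum(top$probability), sum(a$probability) * sum(b$probability) + 1e-12)
  }
})

test_that("the result for k is nested in the result for k + 1 up to boundary ties", {
  set.seed(43)
  a <- isotope_peaks(runif(6, 1, 30), prop.table(runif(6)))
  b <- isotope_peaks(runif(5, 1, 30), prop.table(runif(5)))
  prev <- NULL
  for (k in 1:30) {
    top <- top_isotopologue_pairs(a, b, k)
    if (!is.null(prev)) {
      expect_equal(top$probability[seq_len(k - 1)], prev$probability)
    }
    prev <- top
  }
})

test_that("top_isotopologue_pairs validates k and its inputs", {
  a <- isotope_peaks(12, 1)
  expect_error(top_isotopologue_pairs(a, a, 0), "out of range")
  expect_error(top_isotopologue_pairs(a, a, 2), "out of range")
  expect_error(top_isotopologue_pairs(data.frame(x = 1), a, 1), "expected")
})
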