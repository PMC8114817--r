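Package: lohsum
Title: Optimal Top-k Selection on Cartesian Sums with Layer-Ordered Heaps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects the k smallest values of the Cartesian sum X + Y of two
    numeric vectors in O(n + k) time. The method partitions each input into a
    layer-ordered heap (geometrically growing layers, each layer's maximum no
    larger than the next layer's minimum) using only median-of-medians
    linear-time rank selection, then sweeps the min/max corners of layer
    products with a small priority queue to isolate O(k) candidate sums, and
    finishes with one linear-time k-selection. Includes naive sort- and
    selection-based references, a combinatoric binary-heap enumeration
    baseline, an overshoot benchmark over random uniform integer instances,
    and a mass-spectrometry demonstration that ranks the k most abundant
    combined isotopologue pairs of two molecular fragments via additive
    negative-log abundances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
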