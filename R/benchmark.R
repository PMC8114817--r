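# Overshoot benchmark: how many candidate sums (s + s') the corner sweep
# commits per requested k, over random uniform integer instances at the
# standard (n, k) grid.

#' Random uniform integer instance
#'
#' Draws two independent length-`n` vectors of uniform integers in
#' `[low, high)` (half-open). Reproducible: the RNG is seeded with `seed`
#' on entry (this reseeds the session RNG, as documented).
#'
#' @param n vector length, `>= 1`.
#' @param seed integer RNG seed.
#' @param low,high integer sampling range, `low < high`; values are drawn
#'   from `low, low + 1, ..., high - 1`. Defaults `[0, 2^20)` keep ties
#'   rare at the benchmark sizes.
#' @return A list with numeric vectors `x` and `y`.
#' @export
random_instance <- function(n, seed, low = 0, high = 2^20) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1")
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    stop("need `low < high`")
  }
  set.seed(as.integer(seed))
  span <- high - low
  list(
    x = as.numeric(sample.int(span, n, replace = TRUE) - 1 + low),
    y = as.numeric(sample.int(span, n, replace = TRUE) - 1 + low)
  )
}

#' Standard benchmark configurations
#'
#' The 15 (n, k) pairs of the standard overshoot grid: n in 1000, 2000,
#' 4000, each with five k values from n/4 up to 4n, all at `alpha = 2`.
#'
#' @return A data frame with columns `n`, `k`, `alpha` (15 rows).
#' @export
table1_configs <- function() {
  data.frame(
    n = rep(c(1000L, 2000L, 4000L), each = 5L),
    k = c(250L, 500L, 1000L, 2000L, 4000L,
          500L, 1000L, 2000L, 4000L, 8000L,
          1000L, 2000L, 4000L, 8000L, 16000L),
    alpha = 2
  )
}

#' Overshoot experiment
#'
#' For each configuration and repetition, draws a fresh random uniform
#' integer instance, runs the LOH top-k selection, and records the
#' overshoot ratio `(s + s') / k` — the number of candidate sums the corner
#' sweep committed per requested value. Repetition r uses instance seed
#' `seed + r - 1`, so configurations sharing `n` see identical instances
#' within a repetition (and the LOHification is computed once and reused
#' across their k values).
#'
#' @param configs data frame with columns `n`, `k`, `alpha`; defaults to
#'   [table1_configs()].
#' @param reps repetitions per configuration, `>= 1`.
#' @param seed base RNG seed.
#' @param low,high sampling range passed to [random_instance()].
#' @return A list with `records` (data frame: `n`, `k`, `alpha`, `rep`,
#'   `seed`, `s`, `s_prime`, `ratio`, `t_phase0`, `t_phase123` — timings in
#'   seconds, informational only), `per_config` (mean ratio per
#'   configuration), and `grand_mean_ratio` (mean over configurations of
#'   the per-configuration mean ratios).
#' @examples
#' ex <- overshoot_experiment(data.frame(n = 50, k = 20, alpha = 2), reps = 2, seed = 1)
#' ex$grand_mean_ratio >= 1
#' @export
overshoot_experiment <- function(configs = table1_configs(), reps = 10, seed = 0,
                                 low = 0, high = 2^20) {
  stopifnot(is.data.frame(configs), nrow(configs) > 0L,
            all(c("n", "k", "alpha") %in% names(configs)))
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) stop("`reps` must be >= 1")
  reps <- as.integer(reps)

  rows <- vector("list", nrow(configs) * reps)
  ri <- 0L
  for (r in seq_len(reps)) {
    inst_seed <- as.integer(seed) + r - 1L
    loh_cache <- new.env(parent = emptyenv())
    for (ci in seq_len(nrow(configs))) {
      n <- configs$n[ci]; k <- configs$k[ci]; alpha <- configs$alpha[ci]
      cache_id <- paste(n, alpha, sep = "_")
      entry <- loh_cache[[cache_id]]
      if (is.null(entry)) {
        inst <- random_instance(n, inst_seed, low, high)
        t0 <- proc.time()[["elapsed"]]
        entry <- list(loh_x = lohify(inst$x, alpha), loh_y = lohify(inst$y, alpha))
        entry$t_phase0 <- proc.time()[["elapsed"]] - t0
        loh_cache[[cache_id]] <- entry
      }
      t1 <- proc.time()[["elapsed"]]
      sel <- .select_from_lohs(entry$loh_x, entry$loh_y, as.integer(k), alpha)
      t_phase123 <- proc.time()[["elapsed"]] - t1
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        n = n, k = k, alpha = alpha, rep = r, seed = inst_seed,
        s = sel$trace$s, s_prime = sel$trace$s_prime,
        ratio = (sel$trace$s + sel$trace$s_prime) / k,
        t_phase0 = entry$t_phase0, t_phase123 = t_phase123
      )
    }
  }
  records <- do.call(rbind, rows)
  per_config <- stats::aggregate(ratio ~ n + k + alpha, data = records, FUN = mean)
  list(
    records = records,
    per_config = per_config,
    grand_mean_ratio = mean(per_config$ratio)
  )
}
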