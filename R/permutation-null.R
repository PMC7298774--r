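#' @title Randomized-pair permutation null
#' @description Tests whether a selection-pressure summary of a pattern
#'   class (e.g. the median Ka/Ks of FF pairs) is extreme relative to
#'   equally-sized sets of pairs drawn at random from the full paralog pool.
#' @name permutation_null
NULL

#' Sample a null set of pairs
#'
#' Uniform sample without replacement from the pool.
#'
#' @param pool Vector (or data frame of pairs/estimates) to sample from.
#' @param n Number of pairs to draw; `0 <= n <=` pool size.
#' @return Subset of `pool` (same type), length/row count `n`.
#' @export
sample_null_pairs <- function(pool, n) {
  size <- if (is.data.frame(pool)) nrow(pool) else length(pool)
  if (n > size)
    stop("cannot sample ", n, " pairs from a pool of ", size, call. = FALSE)
  idx <- sample.int(size, n)
  if (is.data.frame(pool)) pool[idx, , drop = FALSE] else pool[idx]
}

.STAT_COLUMN <- c(median_ka_ks = "ka_ks", median_ka = "Ka", median_ks = "Ks",
                  mean_ka_ks = "ka_ks", mean_ka = "Ka", mean_ks = "Ks")

.stat_fun <- function(statistic) {
  if (startsWith(statistic, "median")) {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
}

#' Randomized-pair permutation test
#'
#' Computes the chosen summary statistic on the observed set of pairs, then
#' on `n_reps` random draws of the same number of pairs from the pool
#' (without replacement within a draw, independent across draws). The
#' empirical p-value uses the +1 correction,
#' `p = (#\{null as-or-more extreme\} + 1) / (n_reps + 1)`, so it is never
#' exactly zero and p < 1e-4 is only reportable with at least 10,000
#' replicates. Pairs with undefined values are dropped within each summary.
#'
#' @param observed `kaks_estimates` data frame for the observed set (e.g.
#'   FF pairs), or a numeric vector of statistic inputs.
#' @param pool `kaks_estimates` for the full paralog pool (or numeric
#'   vector).
#' @param statistic One of `median_ka_ks, median_ka, median_ks, mean_ka_ks,
#'   mean_ka, mean_ks` (ignored for numeric-vector input, where the median
#'   or mean is chosen by `vector_stat`).
#' @param n_reps Number of randomized replicates (default 10000).
#' @param tail `"greater"`, `"less"` or `"two_sided"`.
#' @param seed Optional RNG seed for reproducible null draws.
#' @param vector_stat Summary used when inputs are plain numeric vectors
#'   (`"median"` or `"mean"`).
#' @return Object of class `permutation_result`: `observed, null_values,
#'   n_reps, empirical_p, tail, statistic, n_observed, histogram`.
#' @export
permutation_test <- function(observed, pool,
                             statistic = c("median_ka_ks", "median_ka",
                                           "median_ks", "mean_ka_ks",
                                           "mean_ka", "mean_ks"),
                             n_reps = 10000L, tail = c("greater", "less",
                                                       "two_sided"),
                             seed = NULL, vector_stat = c("median", "mean")) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  vector_stat <- match.arg(vector_stat)
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(observed)) {
    col <- .STAT_COLUMN[[statistic]]
    obs_vals <- observed[[col]]
    pool_vals <- pool[[col]]
    fn <- .stat_fun(statistic)
    stat_name <- statistic
  } else {
    obs_vals <- observed
    pool_vals <- pool
    fn <- .stat_fun(vector_stat)
    stat_name <- vector_stat
  }
  if (all(is.na(obs_vals)))
    stop("all observed values are undefined", call. = FALSE)
  if (all(is.na(pool_vals)))
    stop("all pool values are undefined", call. = FALSE)
  n_obs <- length(obs_vals)
  if (n_obs > length(pool_vals))
    stop("observed set larger than pool", call. = FALSE)
  obs_stat <- fn(obs_vals)
  null_values <- vapply(seq_len(n_reps), function(i) {
    fn(pool_vals[sample.int(length(pool_vals), n_obs)])
  }, numeric(1))
  n_ge <- sum(null_values >= obs_stat)
  n_le <- sum(null_values <= obs_stat)
  empirical_p <- switch(tail,
    greater = (n_ge + 1) / (n_reps + 1),
    less = (n_le + 1) / (n_reps + 1),
    two_sided = min(1, 2 * min((n_ge + 1) / (n_reps + 1),
                               (n_le + 1) / (n_reps + 1))))
  hist_lo <- 0.1 * floor(min(null_values, obs_stat, na.rm = TRUE) / 0.1)
  hist_hi <- 0.1 * (floor(max(null_values, obs_stat, na.rm = TRUE) / 0.1) + 1)
  breaks <- seq(hist_lo, hist_hi, by = 0.1)
  idx <- pmin(findInterval(null_values, breaks), length(breaks) - 1L)
  histogram <- data.frame(mid = breaks[-length(breaks)] + 0.05,
                          count = tabulate(idx, nbins = length(breaks) - 1L))
  structure(list(observed = obs_stat, null_values = null_values,
                 n_reps = as.integer(n_reps), empirical_p = empirical_p,
                 tail = tail, statistic = stat_name, n_observed = n_obs,
                 histogram = histogram),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Randomized-pair test (%s, %d observed pairs, %d reps)\n",
              x$statistic, x$n_observed, x$n_reps))
  cat(sprintf("  observed = %.4g, null median = %.4g, empirical p (%s) = %.4g\n",
              x$observed, stats::median(x$null_values), x$tail, x$empirical_p))
  invisible(x)
}

#' @export
plot.permutation_result <- function(x, ...) {
  graphics::hist(x$null_values, breaks = x$histogram$mid |> length() |> max(10),
                 main = sprintf("Null distribution of %s", x$statistic),
                 xlab = x$statistic, col = "navy", border = "white", ...)
  graphics::abline(v = x$observed, col = "red", lty = 2, lwd = 2)
  invisible(x)
}
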