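#' @title Expression-divergence statistics
#' @description Within-pair Pearson correlation, the rescaled correlation r'
#'   used as the expression-divergence measure, ordinary least-squares
#'   regression of r' on Ks, the Mann-Whitney U test, and Ks density
#'   summaries.
#' @name divergence_stats
NULL

#' Pearson product-moment correlation
#'
#' Standard product-moment correlation with explicit handling of the
#' undefined case: zero variance in either vector returns `NA` (an
#' undefined-correlation signal, not an error).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum(xc * yc) / (sx * sy)
  max(-1, min(1, r))
}

#' Within-pair expression correlations
#'
#' @param pairs `paralog_pairs` (or subset of rows).
#' @param expr `expression_matrix`.
#' @param stress Single stress code restricting to that stress's treated
#'   samples, or `NULL` for all treated samples.
#' @return Data frame `pair_id, r, n_samples`; `r` is `NA` where undefined.
#' @export
pair_correlations <- function(pairs, expr, stress = NULL) {
  meta <- expr$sample_meta
  keep <- !meta$is_control
  if (!is.null(stress)) keep <- keep & meta$stress == stress
  cols <- meta$sample[keep]
  if (length(cols) < 3L)
    stop("fewer than 3 treated samples selected", call. = FALSE)
  m <- expr$values[, cols, drop = FALSE]
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!ga %in% rownames(m) || !gb %in% rownames(m))
      stop("gene(s) of pair ", pairs$pair_id[i],
           " absent from expression matrix", call. = FALSE)
    pearson_r(log(m[ga, ] + 1), log(m[gb, ] + 1))
  }, numeric(1))
  data.frame(pair_id = pairs$pair_id, r = r, n_samples = length(cols),
             stringsAsFactors = FALSE)
}

#' Rescaled Pearson coefficient r'
#'
#' The expression-divergence measure used for regression on Ks. The default
#' `"printed"` mode computes `r' = log(1 + r) / (1 - r)`; the `"fisher"`
#' mode computes the Fisher z transform `r' = log((1 + r) / (1 - r))`. Both
#' are strictly monotone in r on (-1, 1), so regression-sign conclusions are
#' identical between modes.
#'
#' @param r Correlation value(s) in `(-1, 1)`; vectorized, `NA` passes
#'   through.
#' @param mode `"printed"` (default) or `"fisher"`.
#' @return Rescaled value(s).
#' @export
rescale_r <- function(r, mode = c("printed", "fisher")) {
  mode <- match.arg(mode)
  bad <- !is.na(r) & (r >= 1 | r <= -1)
  if (any(bad))
    stop("r' undefined at r = ", r[bad][1L],
         " (requires -1 < r < 1)", call. = FALSE)
  if (mode == "printed") log(1 + r) / (1 - r) else log((1 + r) / (1 - r))
}

#' Regress r' on Ks (or Ka)
#'
#' Ordinary least squares of the rescaled correlation on sequence
#' divergence; a negative slope indicates expression divergence increasing
#' with sequence divergence. Pairs with undefined r' or divergence are
#' excluded; their count is reported.
#'
#' @param r_prime Numeric vector of rescaled correlations.
#' @param ks Numeric vector of divergence values (same length).
#' @return List of class `rprime_regression`: `slope, intercept, p_slope,
#'   r_squared, n, n_excluded`.
#' @export
regress_rprime_on_ks <- function(r_prime, ks) {
  if (length(r_prime) != length(ks))
    stop("r_prime and ks must have equal length", call. = FALSE)
  ok <- is.finite(r_prime) & is.finite(ks)
  n_excl <- sum(!ok)
  x <- ks[ok]; y <- r_prime[ok]
  if (length(x) < 3L) stop("need >= 3 pairs with defined r' and Ks",
                           call. = FALSE)
  if (stats::var(x) == 0)
    stop("singular design: all Ks values identical", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate inputs; silence summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 p_slope = unname(sm$coefficients[2L, 4L]),
                 r_squared = sm$r.squared,
                 n = length(x), n_excluded = n_excl),
            class = "rprime_regression")
}

#' @export
print.rprime_regression <- function(x, ...) {
  cat(sprintf("r' ~ Ks OLS: slope = %.4g (p = %.3g), intercept = %.4g, R^2 = %.3f, n = %d\n",
              x$slope, x$p_slope, x$intercept, x$r_squared, x$n))
  if (x$n_excluded > 0)
    cat("  excluded", x$n_excluded, "pair(s) with undefined r' or Ks\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. The two-sided p-value is
#' exact (from the exact null distribution of U) when the smaller sample has
#' at most 8 observations and there are no ties; otherwise the normal
#' approximation with tie correction is used. Complete overlap of tied
#' samples yields p = 1.
#'
#' @param a,b Nonempty numeric vectors.
#' @return List `U` (statistic for sample `a`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)
  if (!has_ties && min(n1, n2) <= 8L) {
    lo <- stats::pwilcox(U, n1, n2)
    hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = unname(U), p = p)
}

#' Histogram summary of Ks values
#'
#' Bins divergence values into left-closed bins of the given width
#' (`[k*w, (k+1)*w)`), reports the modal bin midpoint (smallest midpoint on
#' ties) and the fraction of values exceeding 1.0.
#'
#' @param ks Numeric vector with at least one defined (non-NA) value.
#' @param bin_width Bin width (default 0.1).
#' @return List of class `ks_density`: `breaks, counts, mids, modal_mid,
#'   frac_gt_1, n`.
#' @export
ks_density_summary <- function(ks, bin_width = 0.1) {
  ks <- ks[!is.na(ks)]
  if (length(ks) == 0L) stop("no defined Ks values", call. = FALSE)
  if (any(ks < 0)) stop("Ks values must be >= 0", call. = FALSE)
  upper <- bin_width * (floor(max(ks) / bin_width) + 1L)
  breaks <- seq(0, upper, by = bin_width)
  idx <- pmin(findInterval(ks, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  mids <- breaks[-length(breaks)] + bin_width / 2
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 modal_mid = mids[which.max(counts)],
                 frac_gt_1 = mean(ks > 1), n = length(ks)),
            class = "ks_density")
}

#' @export
print.ks_density <- function(x, ...) {
  cat(sprintf("Ks density (n = %d): modal bin midpoint %.2f; %.1f%% of values > 1.0\n",
              x$n, x$modal_mid, 100 * x$frac_gt_1))
  invisible(x)
}
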