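#' Pearson correlation between concurrently sampled detrended bands
#'
#' Correlates two chronic band-power series (e.g. beta from one
#' hemisphere, theta from the other) after aligning them on their common
#' timestamps (inner join) and, by default, daily detrending by each
#' day's mean — removing slow multi-day drift so the correlation
#' reflects shared within-day fluctuations such as broadband artifacts.
#'
#' @param series_a,series_b [band_power_series] objects.
#' @param detrend Detrend both series with [detrend_daily()] before
#'   correlating (default `TRUE`).
#' @param statistic Daily detrending statistic (default `"mean"`).
#' @return List with `r`, `p_value` (t transform on n - 2 df), `n`.
#' @export
pearson_detrended <- function(series_a, series_b, detrend = TRUE,
                              statistic = "mean") {
  stopifnot(inherits(series_a, "band_power_series"),
            inherits(series_b, "band_power_series"))
  if (detrend) {
    series_a <- detrend_daily(series_a, statistic = statistic)
    series_b <- detrend_daily(series_b, statistic = statistic)
  }
  ka <- as.numeric(series_a$timestamps)
  kb <- as.numeric(series_b$timestamps)
  ia <- match(intersect(ka, kb), ka)
  ib <- match(intersect(ka, kb), kb)
  if (length(ia) < 3L) {
    stop("fewer than 3 common timestamps", call. = FALSE)
  }
  va <- series_a$values[ia]; vb <- series_b$values[ib]
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("zero variance on the common grid", call. = FALSE)
  }
  ct <- cor.test(va, vb, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(va))
}

# Exact null distribution of the positive-rank sum under random signs:
# counts over the support in half-rank units (handles mid-ranks for
# ties), by polynomial convolution. counts[j + 1] = #assignments with
# 2 * W = j; total 2^n.
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  g <- numeric(total + 1L)
  g[1L] <- 1
  for (u in ranks2) {
    shifted <- c(numeric(u), g[seq_len(total + 1L - u)])
    g <- g + shifted
  }
  g
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact test for paired samples in the small-n regime: zeros
#' are dropped, absolute differences are ranked with mid-ranks for ties,
#' W is the sum of ranks of positive differences, and the p-value is
#' computed from the exact null distribution over all 2^n equally likely
#' sign assignments (by convolution over the ranks, equivalent to full
#' enumeration). Two-sided p = 2 min(P(W >= w), P(W <= w)), capped at 1.
#'
#' Either supply paired measurements `a`, `b`, or a precomputed
#' statistic via `statistic` and `n` (assuming untied ranks 1..n).
#'
#' @param a,b Paired numeric vectors.
#' @param statistic Observed positive-rank sum W.
#' @param n Number of non-zero pairs (used with `statistic`).
#' @return A `test_result` list: `statistic` (W), `n`, `p_two_sided`,
#'   `method`.
#' @export
#'
#' @examples
#' wilcoxon_exact(statistic = 43, n = 9)$p_two_sided  # 6/512
wilcoxon_exact <- function(a = NULL, b = NULL, statistic = NULL, n = NULL) {
  if (!is.null(a)) {
    if (is.null(b)) b <- numeric(length(a))
    stopifnot(length(a) == length(b), length(a) >= 2L)
    d <- a - b
    d <- d[d != 0]
    if (!length(d)) stop("all differences are zero", call. = FALSE)
    r <- rank(abs(d))          # mid-ranks for ties
    w <- sum(r[d > 0])
    ranks2 <- round(2 * r)
    n <- length(d)
  } else {
    stopifnot(!is.null(statistic), !is.null(n), n >= 1)
    if (statistic < 0 || statistic > n * (n + 1) / 2) {
      stop("statistic outside [0, n(n+1)/2]", call. = FALSE)
    }
    w <- statistic
    ranks2 <- 2L * seq_len(n)
  }
  if (n > 25L) {
    stop("exact enumeration limited to n <= 25", call. = FALSE)
  }
  cnt <- signed_rank_counts(as.integer(ranks2))
  total <- 2^n
  w2 <- round(2 * w)
  p_ge <- sum(cnt[(w2 + 1L):length(cnt)]) / total
  p_le <- sum(cnt[1L:(w2 + 1L)]) / total
  p <- min(1, 2 * min(p_ge, p_le))
  structure(
    list(statistic = w, n = n, p_two_sided = p,
         p_greater = p_ge, p_less = p_le,
         method = "exact Wilcoxon signed-rank (all sign assignments)"),
    class = "test_result"
  )
}

#' Two-sided p-value of a t statistic
#'
#' @param statistic Observed t.
#' @param df Degrees of freedom.
#' @return Two-sided tail probability.
#' @export
t_two_sided_p <- function(statistic, df) {
  2 * pt(-abs(statistic), df = df)
}

#' Paired t-test
#'
#' Two-sided paired t-test on n - 1 degrees of freedom with a 95%
#' confidence interval for the mean difference (a - b).
#'
#' @param a,b Paired numeric vectors (n >= 2; differences must vary).
#' @param conf_level Confidence level (default 0.95).
#' @return A `test_result` list: `statistic` (t), `df`, `p_two_sided`,
#'   `conf_int`, `mean_difference`, `method`.
#' @export
paired_t <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (sd(d) == 0) stop("zero-variance differences", call. = FALSE)
  tt <- t.test(a, b, paired = TRUE, conf.level = conf_level)
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_two_sided = tt$p.value, conf_int = as.numeric(tt$conf.int),
         mean_difference = unname(tt$estimate),
         method = "paired t-test"),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n", x$method))
  if (!is.null(x$df)) {
    cat(sprintf("  t(%g) = %.4g, p = %.4g\n", x$df, x$statistic,
                x$p_two_sided))
    cat(sprintf("  95%% CI of mean difference: (%.4g, %.4g)\n",
                x$conf_int[1], x$conf_int[2]))
  } else {
    cat(sprintf("  W = %g (n = %d), two-sided p = %.4g\n", x$statistic,
                x$n, x$p_two_sided))
  }
  invisible(x)
}
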