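#' Result of one statistical test
#'
#' Lightweight container holding the statistic, degrees of freedom (where
#' defined), p-value and tail convention of a single test invocation.
#'
#' @param test_name Name of the test.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (`NA` where not applicable).
#' @param p_value p-value in `[0, 1]`.
#' @param tails `"two"`, `"greater"` or `"less"`.
#' @param extra Optional named list of auxiliary quantities.
#' @return Object of class `"stat_result"`.
#' @keywords internal
stat_result <- function(test_name, statistic, df, p_value, tails,
                        extra = list()) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(c(list(test_name = test_name, statistic = statistic, df = df,
                   p_value = p_value, tails = tails), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s (%s-tailed)\n", x$test_name, x$tails))
  cat(sprintf("  statistic = %.6g", x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %.4g", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}

#' Welch's t-test from summary statistics
#'
#' Two-sample location test without the equal-variance assumption, computed
#' from the six summary numbers. The statistic is
#' \deqn{t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}},}
#' with Welch-Satterthwaite degrees of freedom. Tail probabilities are
#' evaluated in log space (`pt(..., log.p = TRUE)`) so extreme statistics do
#' not underflow to an uninformative 0 before doubling.
#'
#' For one-tailed use, `tails = "greater"` tests the alternative
#' `mean1 > mean2` and `"less"` the reverse.
#'
#' @param n1,mean1,sd1 Size, mean and standard deviation of sample 1
#'   (`n1 >= 2`, `sd1 > 0`).
#' @param n2,mean2,sd2 Same for sample 2.
#' @param tails `"two"` (default), `"greater"` or `"less"`.
#' @return A `stat_result` with the t statistic, Welch-Satterthwaite `df` and
#'   p-value.
#' @examples
#' # pooled macronuclear volumes at maximum vs minimum node count
#' welch_t_summary(137, 114000, 43000, 136, 154000, 65000)
#' @export
welch_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                            tails = c("two", "greater", "less")) {
  tails <- match.arg(tails)
  if (n1 < 2 || n2 < 2) stop("both samples must have n >= 2")
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 < 0 || sd2 < 0) {
    stop("standard deviations must be non-negative")
  }
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean1 == mean2) {
      warning("zero variance in both samples with equal means; p = 1 by convention")
      return(stat_result("Welch's t-test", 0, NA_real_, 1, tails))
    }
    stop("zero variance in both samples with unequal means")
  }
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  log_p_upper <- stats::pt(t, df, lower.tail = FALSE, log.p = TRUE)
  log_p_lower <- stats::pt(t, df, lower.tail = TRUE, log.p = TRUE)
  p <- switch(tails,
    two = min(1, 2 * exp(min(log_p_upper, log_p_lower))),
    greater = exp(log_p_upper),
    less = exp(log_p_lower))
  stat_result("Welch's t-test", t, df, p, tails,
              extra = list(mean_diff = mean1 - mean2))
}

#' Welch's t-test from raw samples
#'
#' Identical to [welch_t_summary()] applied to the samples' own sizes, means
#' and standard deviations.
#'
#' @param sample1,sample2 Numeric vectors, each of length `>= 2`.
#' @param tails `"two"` (default), `"greater"` or `"less"`.
#' @return A `stat_result`.
#' @export
welch_t <- function(sample1, sample2, tails = c("two", "greater", "less")) {
  tails <- match.arg(tails)
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  if (length(sample1) < 2 || length(sample2) < 2) {
    stop("both samples must have n >= 2")
  }
  welch_t_summary(length(sample1), mean(sample1), stats::sd(sample1),
                  length(sample2), mean(sample2), stats::sd(sample2),
                  tails = tails)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum distance between the two empirical
#' distribution functions. The p-value uses the asymptotic Kolmogorov
#' distribution \eqn{Q(\lambda) = 2\sum_{k\ge 1} (-1)^{k-1} e^{-2k^2\lambda^2}}
#' evaluated at the standard small-sample-corrected argument
#' \eqn{\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D} with effective
#' size \eqn{n_e = n_1 n_2/(n_1+n_2)} (Numerical Recipes correction).
#'
#' @param sample1,sample2 Numeric vectors, each of length `>= 2`.
#' @return A `stat_result` with statistic `D` and the approximate p-value.
#' @export
ks_2sample <- function(sample1, sample2) {
  sample1 <- sort(sample1[is.finite(sample1)])
  sample2 <- sort(sample2[is.finite(sample2)])
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2) stop("both samples must have n >= 2")
  pts <- sort(unique(c(sample1, sample2)))
  f1 <- findInterval(pts, sample1) / n1
  f2 <- findInterval(pts, sample2) / n2
  d <- max(abs(f1 - f2))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  p <- kolmogorov_q(lambda)
  stat_result("Two-sample Kolmogorov-Smirnov test", d, NA_real_, p, "two",
              extra = list(effective_n = ne))
}

#' Complementary CDF of the Kolmogorov distribution
#' @keywords internal
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  terms <- vapply(1:100, function(k) {
    (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
  }, numeric(1))
  min(1, max(0, 2 * sum(terms)))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank handling of ties. `U` is reported for sample 1:
#' `U = R1 - n1(n1+1)/2`, so `U = 0` when every value of sample 1 lies below
#' every value of sample 2 and `U = n1*n2` in the opposite extreme. When the
#' data are tie-free and `n1 * n2 <= 400` the p-value is exact, from the
#' count recursion for the null distribution of `U` (equivalent to full
#' enumeration of rank assignments); otherwise a normal approximation with
#' tie correction and continuity correction is used.
#'
#' `tails = "greater"` tests the alternative that sample 1 is stochastically
#' larger than sample 2.
#'
#' @param sample1,sample2 Numeric vectors, each of length `>= 2`.
#' @param tails `"two"` (default), `"greater"` or `"less"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact null; `NULL`
#'   (default) auto-selects as described.
#' @return A `stat_result` with `U`, the p-value, and whether the exact null
#'   was used (`$exact`).
#' @export
mann_whitney_u <- function(sample1, sample2,
                           tails = c("two", "greater", "less"),
                           exact = NULL) {
  tails <- match.arg(tails)
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 2 || n2 < 2) stop("both samples must have n >= 2")
  pooled <- c(sample1, sample2)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- if (is.null(exact)) !has_ties && n1 * n2 <= 400 else exact
  if (use_exact && has_ties) {
    warning("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    cdf <- wilcox_count_cdf(n1, n2)          # P(U <= u), u = 0..n1*n2
    p_le <- cdf[u + 1]
    p_ge <- if (u >= 1) 1 - cdf[u] else 1
    p <- switch(tails,
      two = min(1, 2 * min(p_le, p_ge)),
      greater = p_ge,
      less = p_le)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else {
      z_ge <- (u - mu - 0.5) / sigma
      z_le <- (u - mu + 0.5) / sigma
      p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
      p_le <- stats::pnorm(z_le)
      p <- switch(tails,
        two = min(1, 2 * min(p_le, p_ge)),
        greater = p_ge,
        less = p_le)
    }
  }
  stat_result("Mann-Whitney U test", u, NA_real_, p, tails,
              extra = list(exact = use_exact))
}

#' Exact null CDF of the Mann-Whitney U statistic
#'
#' Dynamic-programming count of rank configurations (`c(u; m, n) =
#' c(u - n; m - 1, n) + c(u; m, n - 1)`), normalized by `choose(m + n, m)`.
#' Equivalent to enumerating all arrangements, without the factorial cost.
#'
#' @param n1,n2 Sample sizes.
#' @return Numeric vector of `P(U <= u)` for `u = 0..n1*n2`.
#' @keywords internal
wilcox_count_cdf <- function(n1, n2) {
  umax <- n1 * n2
  zero <- rep(0, umax + 1)
  e0 <- c(1, rep(0, umax))
  # dp[[i + 1]][u + 1] = N(u; i, j) for the current j:
  # number of interleavings of i sample-1 and j sample-2 values with U = u.
  # Recurrence on the largest remaining value:
  #   N(u; i, j) = N(u - j; i - 1, j) + N(u; i, j - 1)
  dp <- c(list(e0), rep(list(e0), n1))    # j = 0: U is always 0
  for (j in seq_len(n2)) {
    newdp <- vector("list", n1 + 1)
    newdp[[1]] <- e0
    for (i in seq_len(n1)) {
      shifted <- if (j <= umax) c(rep(0, j), newdp[[i]][seq_len(umax + 1 - j)])
                 else zero
      newdp[[i + 1]] <- shifted + dp[[i + 1]]
    }
    dp <- newdp
  }
  counts <- dp[[n1 + 1]]
  cumsum(counts) / sum(counts)
}

#' Mean with 95% confidence interval
#'
#' t-based interval: halfwidth `qt(0.975, n - 1) * sd / sqrt(n)`.
#'
#' @param sample Numeric vector of length `>= 2`.
#' @return List with `mean`, `halfwidth`, `n`.
#' @export
mean_ci95 <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 2) stop("need at least 2 observations for a confidence interval")
  hw <- stats::qt(0.975, n - 1) * stats::sd(sample) / sqrt(n)
  list(mean = mean(sample), halfwidth = hw, n = n)
}
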