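# Statistical primitives shared by the discordance analyses.
#
# All of these are small, exact-where-stated procedures: the confidence
# interval machinery is Clopper-Pearson (beta quantiles), multiple
# comparisons of proportions use the Marascuilo chi-square critical range,
# multiple comparisons of means use a Dunnett-Tukey-Kramer construction
# valid under unequal n and unequal variances, and the univariate screens
# rely on Woolf-interval odds ratios and the rank-sum test.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion from beta quantiles:
#' lower bound `qbeta(alpha/2, x, n - x + 1)`, upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)`, with the conventional closures
#' `low = 0` when `x = 0` and `high = 1` when `x = n`.
#'
#' @param x Number of successes (non-negative integer).
#' @param n Number of trials (positive integer).
#' @param level Two-sided confidence level, default 0.95.
#' @return A list of class `dr_exact_ci` with elements `x`, `n`, `estimate`,
#'   `low`, `high`, `level`.
#' @examples
#' clopper_pearson(362, 1724)  # [0.191, 0.230]
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L)
  if (is.na(x) || is.na(n) || n <= 0) stop("clopper_pearson: n must be > 0")
  if (x < 0 || x > n) stop("clopper_pearson: need 0 <= x <= n")
  alpha <- 1 - level
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  structure(
    list(x = as.integer(x), n = as.integer(n), estimate = x / n,
         low = low, high = high, level = level),
    class = "dr_exact_ci"
  )
}

#' @export
print.dr_exact_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% [%0.1f; %0.1f]%% (%g%% Clopper-Pearson)\n",
              x$x, x$n, 100 * x$estimate, 100 * x$low, 100 * x$high,
              100 * x$level))
  invisible(x)
}

#' Marascuilo procedure for multiple comparisons of proportions
#'
#' Compares all pairs of group proportions simultaneously: the pair (i, j)
#' is significant when `|p_i - p_j|` exceeds
#' `sqrt(qchisq(1 - alpha, k - 1)) * sqrt(p_i(1-p_i)/n_i + p_j(1-p_j)/n_j)`.
#'
#' @param x Vector of success counts per group.
#' @param n Vector of group sizes (same length, all > 0).
#' @param alpha Family-wise significance level, default 0.05.
#' @param labels Optional group labels.
#' @return Data frame with one row per pair: the two groups, the absolute
#'   difference in proportions, the critical range, and a `significant` flag.
#' @export
marascuilo <- function(x, n, alpha = 0.05, labels = NULL) {
  stopifnot(length(x) == length(n), length(x) >= 2L)
  if (any(n <= 0)) stop("marascuilo: all group sizes must be > 0")
  k <- length(x)
  p <- x / n
  if (is.null(labels)) labels <- as.character(seq_len(k))
  chi <- sqrt(qchisq(1 - alpha, df = k - 1))
  pairs <- combn(k, 2)
  out <- data.frame(
    group1 = labels[pairs[1, ]],
    group2 = labels[pairs[2, ]],
    diff = abs(p[pairs[1, ]] - p[pairs[2, ]]),
    critical = chi * sqrt(p[pairs[1, ]] * (1 - p[pairs[1, ]]) / n[pairs[1, ]] +
                          p[pairs[2, ]] * (1 - p[pairs[2, ]]) / n[pairs[2, ]]),
    stringsAsFactors = FALSE
  )
  out$significant <- out$diff > out$critical
  out
}

#' Dunnett-Tukey-Kramer pairwise mean-difference intervals
#'
#' Simultaneous confidence intervals for all pairwise mean differences under
#' unequal sample sizes and unequal variances: each pair uses the studentized
#' range quantile at Welch-Satterthwaite degrees of freedom,
#' `diff +- qtukey(1 - alpha, k, df_ij) / sqrt(2) * sqrt(s_i^2/n_i + s_j^2/n_j)`.
#'
#' @param groups List of numeric vectors, each with at least 2 values.
#' @param alpha Family-wise level, default 0.05.
#' @return Data frame with one row per pair: mean difference, lower and upper
#'   simultaneous bounds, and a `significant` flag (interval excludes 0).
#' @export
dtk_pairwise <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("dtk_pairwise: every group needs >= 2 values")
  if (any(vapply(groups, sd, 1) == 0))
    stop("dtk_pairwise: degenerate (zero-variance) group")
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  m <- vapply(groups, mean, 1)
  v <- vapply(groups, var, 1)
  n <- vapply(groups, length, 1L)
  pairs <- combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    q <- stats::qtukey(1 - alpha, nmeans = k, df = df) / sqrt(2)
    d <- m[i] - m[j]
    c(d, d - q * sqrt(se2), d + q * sqrt(se2))
  })
  out <- data.frame(
    group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
    diff = res[1, ], low = res[2, ], high = res[3, ],
    stringsAsFactors = FALSE
  )
  out$significant <- out$low > 0 | out$high < 0
  out
}

#' Wilcoxon rank-sum test (two independent samples)
#'
#' Rank-sum test of a location difference between two samples.  For combined
#' sample size at most `exact_max` (default 12) the null distribution is
#' enumerated exhaustively over all assignments of the pooled (mid)ranks;
#' above that, a normal approximation with tie correction is used.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest combined n for which enumeration is used.
#' @return List with `statistic` (rank sum of `a`), `p.value`, and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b)) stop("wilcoxon_rank_sum: empty sample")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = sum(rank(pooled)[seq_along(a)]), p.value = 1,
                method = "degenerate (all tied)"))
  r <- rank(pooled)
  na <- length(a); nb <- length(b); n <- na + nb
  w <- sum(r[seq_len(na)])
  if (n <= exact_max) {
    sets <- combn(n, na)
    ws <- colSums(matrix(r[sets], nrow = na))
    p <- 2 * min(mean(ws <= w), mean(ws >= w))
    return(list(statistic = w, p.value = min(1, p),
                method = "exact enumeration"))
  }
  mu <- na * (n + 1) / 2
  ties <- table(r)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
  list(statistic = w, p.value = min(1, 2 * pnorm(-abs(z))),
       method = "normal approximation with tie correction")
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the log-normal (Woolf)
#' interval `exp(log(OR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald
#' p-value on the log scale.  When any cell is zero the Haldane-Anscombe
#' 0.5 correction is applied to every cell and the result is flagged.
#'
#' @param a,b,c,d Cell counts: `a` = exposed & event, `b` = exposed &
#'   no event, `c` = unexposed & event, `d` = unexposed & no event.
#' @param level Confidence level, default 0.95.
#' @return List with `or`, `low`, `high`, `p.value`, `corrected`.
#'   `or` is `NA` when a full row or column is zero (undefined).
#' @export
odds_ratio <- function(a, b, c, d, level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("odds_ratio: cells must be non-negative integers")
  undefined <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  if (undefined)
    return(list(or = NA_real_, low = NA_real_, high = NA_real_,
                p.value = NA_real_, corrected = FALSE))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  lo <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(lo), low = exp(lo - z * se), high = exp(lo + z * se),
       p.value = 2 * pnorm(-abs(lo / se)), corrected = corrected)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples `values` with replacement `B` times, applies `statistic`, and
#' returns the percentile interval.  Resamples on which the statistic is
#' not finite are redrawn (at most `max_retries` times in total).
#'
#' @param values Numeric vector (or rows indexable object) to resample.
#' @param statistic Function of a resampled vector; default `mean`.
#' @param B Number of bootstrap resamples, default 2000.
#' @param level Confidence level, default 0.95.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `estimate`, `low`, `high`, `B`.
#' @export
bootstrap_ci <- function(values, statistic = mean, B = 2000L, level = 0.95,
                         seed = NULL, max_retries = 100L) {
  n <- length(values)
  if (n < 2L) stop("bootstrap_ci: need >= 2 observations")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stat <- numeric(B)
  retries <- 0L
  for (i in seq_len(B)) {
    repeat {
      s <- statistic(values[sample.int(n, n, replace = TRUE)])
      if (is.finite(s)) break
      retries <- retries + 1L
      if (retries > max_retries) stop("bootstrap_ci: statistic undefined on too many resamples")
    }
    stat[i] <- s
  }
  alpha <- 1 - level
  qs <- quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  list(estimate = statistic(values), low = qs[1], high = qs[2], B = B)
}

#' McNemar test for paired binary outcomes
#'
#' Tests marginal homogeneity from the two discordant cells of a paired
#' 2x2 table.  For `b + c < exact_max` (default 25) the exact binomial
#' two-sided tail-doubling p-value is used; otherwise the chi-square
#' statistic with continuity correction.
#'
#' @param b,c The two discordant cell counts.
#' @param exact_max Threshold on `b + c` below which the exact test is used.
#' @return List with `statistic` (NA for the exact branch), `p.value`,
#'   `method`.
#' @export
mcnemar_test <- function(b, c, exact_max = 25L) {
  stopifnot(b >= 0, c >= 0)
  m <- b + c
  if (m == 0) return(list(statistic = 0, p.value = 1, method = "degenerate"))
  if (m < exact_max) {
    p <- min(1, 2 * pbinom(min(b, c), m, 0.5))
    return(list(statistic = NA_real_, p.value = p, method = "exact binomial"))
  }
  stat <- (abs(b - c) - 1)^2 / m
  list(statistic = stat, p.value = 1 - stats::pchisq(stat, df = 1),
       method = "chi-square with continuity correction")
}
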