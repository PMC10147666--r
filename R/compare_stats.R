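#' Significance stars for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, otherwise `"ns"`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

test_result <- function(test_name, statistic, df, p_value, term = NA_character_) {
  structure(list(test_name = test_name, term = term, statistic = statistic,
                 df = df, p_value = p_value,
                 stars = significance_stars(p_value)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s%s: stat %.4g, df %s, p %.4g %s\n",
              x$test_name,
              if (!is.na(x$term)) paste0(" [", x$term, "]") else "",
              x$statistic, paste(signif(x$df, 5), collapse = ","),
              x$p_value, x$stars))
  invisible(x)
}

#' Boxplot five-number summary with Tukey hinges
#'
#' Hinges are the first and third quartiles in the Tukey-hinge convention
#' (as drawn by default boxplots); whiskers extend from each hinge to the
#' most extreme data point within 1.5 x IQR of it, and points beyond the
#' whiskers are outliers. A linear-interpolation quartile convention is
#' available behind `quartile = "linear"`.
#'
#' @param values Non-empty numeric vector.
#' @param quartile `"tukey"` (default) or `"linear"` (type-7 quantiles).
#' @return A `boxplot_summary`: median, lower_hinge, upper_hinge,
#'   lower_whisker, upper_whisker, outliers.
#' @export
boxplot_summary <- function(values, quartile = c("tukey", "linear")) {
  quartile <- match.arg(quartile)
  values <- as.numeric(values)
  if (length(values) == 0 || any(!is.finite(values)))
    stop("boxplot_summary requires >= 1 finite value")
  if (quartile == "tukey") {
    fn <- fivenum(values)
    lh <- fn[2]; med <- fn[3]; uh <- fn[4]
  } else {
    q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    lh <- q[1]; med <- q[2]; uh <- q[3]
  }
  iqr <- uh - lh
  in_lo <- values >= lh - 1.5 * iqr
  in_hi <- values <= uh + 1.5 * iqr
  structure(list(median = med, lower_hinge = lh, upper_hinge = uh,
                 lower_whisker = min(values[in_lo]),
                 upper_whisker = max(values[in_hi]),
                 outliers = sort(values[!(in_lo & in_hi)])),
            class = "boxplot_summary")
}

#' Welch two-sample t-test (unequal variances)
#'
#' Two-sided Welch t statistic with Welch–Satterthwaite degrees of freedom:
#' `t = (mean_a - mean_b) / sqrt(va/na + vb/nb)`.
#'
#' @param a,b Numeric vectors, each with >= 2 values; at least one group
#'   must have nonzero variance.
#' @return A `test_result` (`test_name = "welch_t"`).
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("welch_t requires >= 2 values per group")
  va <- var(a) / na
  vb <- var(b) / nb
  if (va + vb == 0)
    stop("welch_t undefined: both groups have zero variance")
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(tt), df)
  test_result("welch_t", tt, df, p)
}

#' One-way ANOVA (fixed effects)
#'
#' Classical between/within decomposition: `F = MS_between / MS_within`.
#' A constant response (zero total sum of squares) is reported as
#' statistic 0 with p = 1 by convention.
#'
#' @param values Numeric response.
#' @param group Factor (or coercible) with >= 2 levels; residual df >= 1.
#' @return A `test_result` (`test_name = "anova_1way"`).
#' @export
anova_oneway <- function(values, group) {
  values <- as.numeric(values)
  group <- factor(group)
  k <- nlevels(group)
  n <- length(values)
  if (k < 2) stop("one-way ANOVA requires a factor with >= 2 levels")
  if (n - k < 1) stop("one-way ANOVA requires residual df >= 1")
  gm <- mean(values)
  means <- tapply(values, group, mean)
  ns <- tabulate(group)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[group])^2)
  if (ssb + ssw == 0)
    return(test_result("anova_1way", 0, c(k - 1, n - k), 1))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  test_result("anova_1way", f, c(k - 1, n - k), p)
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Fits `y ~ A * B` by least squares and forms Type II sums of squares via
#' model comparison: `SS(A | B)`, `SS(B | A)`, and `SS(AB | A + B)`, each
#' tested against the full-model residual mean square. Type II is used
#' because replicate counts may be unbalanced across the condition grid. A
#' constant response is reported with p = 1 per term by convention.
#'
#' @param values Numeric response.
#' @param f1,f2 The two factors (>= 2 levels each).
#' @param names Labels for the two factors in the output.
#' @return A list of three `test_result`s (terms: f1, f2, interaction).
#' @export
anova_twoway <- function(values, f1, f2, names = c("A", "B")) {
  y <- as.numeric(values)
  f1 <- factor(f1); f2 <- factor(f2)
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stop("two-way ANOVA requires >= 2 levels per factor")
  rss <- function(fml) sum(stats::residuals(stats::lm(fml))^2)
  rss_full <- rss(y ~ f1 * f2)
  rss_add <- rss(y ~ f1 + f2)
  ss <- c(f1 = rss(y ~ f2) - rss_add,
          f2 = rss(y ~ f1) - rss_add,
          interaction = rss_add - rss_full)
  df_full <- stats::df.residual(stats::lm(y ~ f1 * f2))
  if (df_full < 1) stop("two-way ANOVA requires residual df >= 1")
  df_terms <- c(nlevels(f1) - 1, nlevels(f2) - 1,
                (nlevels(f1) - 1) * (nlevels(f2) - 1))
  terms <- c(names, paste(names, collapse = ":"))
  if (var(y) == 0) {
    return(lapply(seq_along(terms), function(i)
      test_result("anova_2way", 0, c(df_terms[i], df_full), 1, terms[i])))
  }
  mse <- rss_full / df_full
  tss <- sum((y - mean(y))^2)
  lapply(seq_along(terms), function(i) {
    if (mse <= 1e-12 * tss) {
      # saturated (noise-free) layout: a term with zero incremental SS has
      # no effect (F reported 0, p 1); a nonzero term is infinitely strong
      null_term <- ss[i] <= 1e-12 * tss
      f <- if (null_term) 0 else Inf
      p <- if (null_term) 1 else 0
    } else {
      f <- (ss[i] / df_terms[i]) / mse
      p <- pf(f, df_terms[i], df_full, lower.tail = FALSE)
    }
    test_result("anova_2way", unname(f), c(df_terms[i], df_full),
                unname(p), terms[i])
  })
}

#' Ratio of group means between two timepoints
#'
#' The late/early comparison used for in vivo day-15 vs day-3 contrasts:
#' `mean(day_late) / mean(day_early)`.
#'
#' @param day_late,day_early Numeric vectors with positive means.
#' @return The ratio of means.
#' @export
timepoint_ratio <- function(day_late, day_early) {
  me <- mean(day_early)
  ml <- mean(day_late)
  if (me <= 0) stop("early-timepoint mean must be positive")
  if (ml <= 0) stop("late-timepoint mean must be positive")
  ml / me
}
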