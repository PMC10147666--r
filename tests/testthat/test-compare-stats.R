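test_that("boxplot summary uses Tukey hinges and 1.5 IQR whiskers", {
  # Tukey hinges of 1:7 (hinge depth 2.5): average of 2nd/3rd and 5th/6th
  b <- boxplot_summary(1:7)
  expect_equal(b$median, 4)
  expect_equal(c(b$lower_hinge, b$upper_hinge), fivenum(1:7)[c(2, 4)])
  expect_equal(c(b$lower_hinge, b$upper_hinge), c(2.5, 5.5))
  expect_equal(c(b$lower_whisker, b$upper_whisker), c(1, 7))
  expect_length(b$outliers, 0)

  # all-equal input degenerates to a single point
  bc <- boxplot_summary(rep(3.5, 6))
  expect_equal(unlist(bc[c("median", "lower_hinge", "upper_hinge",
                           "lower_whisker", "upper_whisker")]),
               rep(3.5, 5), ignore_attr = TRUE)

  # {1,2,3,4,100}: hinges 2 and 4, fence at 4 + 1.5*2 = 7 -> 100 outlying
  bo <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_equal(bo$upper_whisker, 4)
  expect_equal(bo$outliers, 100)
  expect_error(boxplot_summary(numeric(0)), "value")
})

test_that("linear-quartile convention is available and differs when it should", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  bt <- boxplot_summary(x, quartile = "tukey")
  bl <- boxplot_summary(x, quartile = "linear")
  expect_equal(bt$lower_hinge, 2.5)                 # Tukey hinge
  expect_equal(bl$lower_hinge, quantile(x, 0.25, names = FALSE))  # type 7
  expect_false(bt$lower_hinge == bl$lower_hinge)
})

test_that("boxplot invariant chain holds on random samples", {
  set.seed(99)
  for (i in 1:1000) {
    x <- rnorm(sample(1:30, 1), sd = sample(c(0.1, 1, 10), 1))
    b <- boxplot_summary(x)
    expect_true(b$lower_whisker <= b$lower_hinge &&
                  b$lower_hinge <= b$median &&
                  b$median <= b$upper_hinge &&
                  b$upper_hinge <= b$upper_whisker)
  }
})

test_that("Welch t matches its definition and symmetries", {
  a <- c(-1, 0, 1); b <- c(-2, 0, 2)
  w <- welch_t(a, b)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  # translation invariance
  w1 <- welch_t(c(1, 2, 3), c(2, 3, 4.5))
  w2 <- welch_t(c(1, 2, 3) + 11.3, c(2, 3, 4.5) + 11.3)
  expect_equal(w1$statistic, w2$statistic)
  expect_equal(w1$p_value, w2$p_value)
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Welch t agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    w <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("one-way ANOVA agrees with aov and handles degenerate input", {
  set.seed(13)
  for (i in 1:20) {
    g <- factor(rep(seq_len(sample(2:4, 1)), each = sample(3:6, 1)))
    y <- rnorm(length(g)) + as.numeric(g) * runif(1)
    got <- anova_oneway(y, g)
    ref <- summary(aov(y ~ g))[[1]]
    expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
  }
  const <- anova_oneway(rep(2, 6), factor(rep(1:2, 3)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(anova_oneway(rnorm(4), factor(rep("a", 4))), "2 levels")
})

test_that("two-way Type II ANOVA agrees with the reference implementation", {
  set.seed(29)
  for (i in 1:20) {
    # unbalanced layouts included: replicate counts vary per cell
    cells <- expand.grid(A = factor(c("a1", "a2")),
                         B = factor(paste0("b", seq_len(sample(2:3, 1)))))
    reps <- sample(2:5, nrow(cells), replace = TRUE)
    d <- cells[rep(seq_len(nrow(cells)), reps), ]
    d$y <- rnorm(nrow(d)) + as.numeric(d$A) * runif(1) +
      as.numeric(d$B) * runif(1)
    got <- anova_twoway(d$y, d$A, d$B)
    ref <- car::Anova(lm(y ~ A * B, data = d), type = 2)
    for (k in 1:3) {
      expect_equal(got[[k]]$statistic, ref$`F value`[k], tolerance = 1e-8)
      expect_equal(got[[k]]$p_value, ref$`Pr(>F)`[k], tolerance = 1e-8)
    }
  }
})

test_that("noise-free additive two-factor layout has a null interaction", {
  d <- expand.grid(A = factor(c("a1", "a2")), B = factor(c("b1", "b2")),
                   rep = 1:3)
  d$y <- c(a1 = 0, a2 = 2)[d$A] + c(b1 = 0, b2 = 5)[d$B]
  res <- anova_twoway(d$y, d$A, d$B)
  inter <- res[[3]]
  expect_equal(inter$statistic, 0)
  expect_equal(inter$p_value, 1)
  # constant response: every term reports p = 1 by convention
  resc <- anova_twoway(rep(1, nrow(d)), d$A, d$B)
  expect_true(all(vapply(resc, function(t) t$p_value, numeric(1)) == 1))
})

test_that("star assignment is a pure threshold function of p", {
  p <- c(0.2, 0.049999, 0.05, 0.009, 0.01, 0.0009, 0.001, 0)
  expect_equal(significance_stars(p),
               c("ns", "*", "ns", "**", "*", "***", "**", "***"))
})

test_that("timepoint ratio of means behaves as a scale-free ratio", {
  expect_equal(timepoint_ratio(c(10, 20, 30), c(1, 2, 3)), 10)
  expect_equal(timepoint_ratio(c(2, 2), c(2, 2)), 1)
  expect_equal(timepoint_ratio(c(10, 20) * 3.7, c(5, 5) * 3.7),
               timepoint_ratio(c(10, 20), c(5, 5)))
  expect_error(timepoint_ratio(c(1, 2), c(0, 0)), "positive")
})
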