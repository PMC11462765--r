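# Independent oracles, written before the implementations they check.

# AUROC by exhaustive positive-negative pair comparison (ties count 1/2)
auroc_oracle <- function(y, s) {
  pos <- s[y]; neg <- s[!y]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Average precision by explicit threshold enumeration
auprc_oracle <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in thr) {
    pred <- s >= t
    tp <- sum(y & pred); fp <- sum(!y & pred)
    rec <- tp / sum(y); prec <- tp / (tp + fp)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# The combined 5x2 CV F statistic, transcribed independently
ftest_oracle <- function(a, b) {
  p <- a - b
  num <- sum(p^2)
  den <- 0
  for (i in 1:5) {
    pb <- (p[i, 1] + p[i, 2]) / 2
    den <- den + (p[i, 1] - pb)^2 + (p[i, 2] - pb)^2
  }
  f <- num / (2 * den)
  list(f = f, p = 1 - pf(f, 10, 5))
}

test_that("confusion-matrix metrics match closed forms", {
  # TP=3, FP=1, TN=5, FN=1
  y <- c(rep("CASE", 4), rep("NON_CASE", 6))
  pred <- c("CASE", "CASE", "CASE", "NON_CASE",
            "CASE", rep("NON_CASE", 5))
  m <- threshold_metrics(y, pred)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6, tolerance = 1e-12)
  expect_equal(m$f1, 0.75)

  perfect <- threshold_metrics(y, y)
  expect_equal(unlist(perfect), c(accuracy = 1, f1 = 1, ppv = 1, npv = 1))

  none_pos <- threshold_metrics(y, rep("NON_CASE", 10))
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$accuracy, 0.6)
  expect_false(is.na(none_pos$npv))

  expect_error(threshold_metrics(character(0), character(0)),
               class = "em_input_error")
})

test_that("the worked ROC/PR example reproduces to high precision", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.4, 0.35, 0.8)
  cm <- curve_metrics(y, s)
  expect_equal(cm$auroc, 0.75, tolerance = 1e-12)
  expect_equal(cm$auprc, 0.5 + 0.5 * 2 / 3, tolerance = 1e-12)

  sep <- curve_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auroc, 1)
  expect_equal(sep$auprc, 1)

  expect_error(curve_metrics(c(1, 1), c(0.2, 0.3)),
               class = "em_undefined_curve_error")
})

test_that("AUROC equals the exhaustive pairwise statistic on random instances", {
  set.seed(50)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    expect_equal(curve_metrics(y, s)$auroc, auroc_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("AUPRC equals the hand-coded average-precision oracle", {
  set.seed(51)
  for (i in 1:400) {
    n <- sample(4:30, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    s <- round(runif(n), sample(1:3, 1))
    expect_equal(curve_metrics(y, s)$auprc, auprc_oracle(y, s), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established implementation", {
  set.seed(52)
  y <- runif(60) < 0.4; y[1:2] <- c(TRUE, FALSE)
  s <- round(runif(60), 2)
  expect_equal(curve_metrics(y, s)$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-9)
})

test_that("AUPRC of random scores converges to the label prevalence", {
  set.seed(53)
  y <- runif(10000) < 0.3
  s <- runif(10000)
  expect_equal(curve_metrics(y, s)$auprc, mean(y), tolerance = 0.02)
})

test_that("fold summaries are mean +/- sample SD with the documented rendering", {
  folds <- data.frame(fold = 1:2, auroc = c(0.8, 0.9))
  s <- summarize_folds(folds)
  expect_equal(s$mean[s$metric == "auroc"], 0.85)
  expect_equal(s$sd[s$metric == "auroc"], sd(c(0.8, 0.9)), tolerance = 1e-12)
  expect_equal(s$rendered[s$metric == "auroc"], "0.85 ± 0.07")

  ident <- summarize_folds(data.frame(fold = 1:3, acc = rep(0.7, 3)))
  expect_equal(ident$sd, 0)

  # two-pass reference computation
  set.seed(54)
  v <- runif(10)
  s2 <- summarize_folds(data.frame(fold = 1:10, m = v))
  expect_equal(s2$mean[s2$metric == "m"], sum(v) / 10, tolerance = 1e-15)
  expect_equal(s2$sd[s2$metric == "m"], sqrt(sum((v - mean(v))^2) / 9), tolerance = 1e-15)

  # undefined folds are excluded with a warning
  folds <- data.frame(fold = 1:10, ppv = c(NA, runif(9)))
  expect_warning(s3 <- summarize_folds(folds), "undefined")
  expect_equal(s3$n_defined[s3$metric == "ppv"], 9)
  expect_equal(s3$mean[s3$metric == "ppv"], mean(folds$ppv, na.rm = TRUE))

  expect_error(summarize_folds(data.frame(fold = 1, auroc = 0.9)),
               class = "em_input_error")
})

test_that("the combined 5x2 CV F statistic matches the formula oracle", {
  # the worked example
  a <- matrix(c(0.8, 0.85, 0.8, 0.9, 0.75, 0.9, 0.8, 0.85, 0.9, 0.85), 5, 2, byrow = TRUE)
  d <- matrix(c(0.1, 0.2, 0.15, 0.05, 0.0, 0.1, 0.2, 0.1, 0.05, 0.15), 5, 2, byrow = TRUE)
  b <- a - d
  r <- five_by_two_cv_ftest(a, b)
  o <- ftest_oracle(a, b)
  expect_equal(r$statistic, o$f, tolerance = 1e-12)
  expect_equal(r$p.value, o$p, tolerance = 1e-12)
  expect_equal(r$df, c(10, 5))

  set.seed(55)
  for (i in 1:200) {
    a <- matrix(runif(10, 0.5, 1), 5, 2)
    b <- matrix(runif(10, 0.5, 1), 5, 2)
    r <- five_by_two_cv_ftest(a, b)
    o <- ftest_oracle(a, b)
    expect_equal(r$statistic, o$f, tolerance = 1e-12)
    expect_equal(r$p.value, o$p, tolerance = 1e-12)
    # swapping the models leaves the statistic unchanged
    expect_equal(five_by_two_cv_ftest(b, a)$statistic, r$statistic, tolerance = 1e-12)
  }
})

test_that("degenerate and malformed F-test inputs error", {
  a <- matrix(0.8, 5, 2)
  expect_error(five_by_two_cv_ftest(a, a), class = "em_degenerate_variance_error")
  expect_error(five_by_two_cv_ftest(matrix(0.8, 4, 2), matrix(0.7, 4, 2)),
               class = "em_input_error")
})

test_that("the F-test is valid (conservative) under a simulated null", {
  # With i.i.d. normal accuracy differences the statistic decomposes as
  # F = 0.5 * F(5,5) + 0.5, so its exact size at nominal alpha = 0.05 is
  # P(F(5,5) > 2 * (q - 0.5)) ~= 0.0175: below nominal, never above.
  exact <- pf(2 * (qf(0.95, 10, 5) - 0.5), 5, 5, lower.tail = FALSE)
  set.seed(56)
  reject <- replicate(1000, {
    d <- matrix(rnorm(10, 0, 0.05), 5, 2)  # i.i.d. accuracy differences
    base <- matrix(0.8, 5, 2)
    five_by_two_cv_ftest(base + d, base)$p.value < 0.05
  })
  rate <- mean(reject)
  expect_lte(rate, 0.05)  # never anti-conservative
  # within the 99.9% binomial band of the exact size
  band <- qbinom(c(5e-4, 1 - 5e-4), 1000, exact) / 1000
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})
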