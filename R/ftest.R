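# Combined 5x2-fold cross-validation F-test for comparing two learning
# algorithms. With accuracy difference p_i^(j) on fold j of replication i,
# replication mean pbar_i and variance s_i^2 = (p_i^(1) - pbar_i)^2 +
# (p_i^(2) - pbar_i)^2, the statistic
#   F = sum_i sum_j (p_i^(j))^2 / (2 * sum_i s_i^2)
# is referred to the F distribution with (10, 5) degrees of freedom.

#' Combined 5x2 CV F-test from accuracy matrices
#'
#' @param acc_a,acc_b 5 x 2 matrices of per-fold accuracies for models A and
#'   B: row = replication (a 2-fold CV), column = fold.
#' @return Object of class `ftest_5x2`: `statistic`, `df = c(10, 5)`,
#'   `p.value`, the fold-wise differences `diffs`, and per-replication
#'   variances `s2`.
#' @export
five_by_two_cv_ftest <- function(acc_a, acc_b) {
  acc_a <- as.matrix(acc_a); acc_b <- as.matrix(acc_b)
  if (!all(dim(acc_a) == c(5, 2)) || !all(dim(acc_b) == c(5, 2)))
    em_stop("em_input_error", "need 5 x 2 accuracy matrices for both models")
  p <- acc_a - acc_b
  pbar <- rowMeans(p)
  s2 <- (p[, 1] - pbar)^2 + (p[, 2] - pbar)^2
  if (sum(s2) <= 0)
    em_stop("em_degenerate_variance_error",
            "all replication-wise accuracy differences are constant; F undefined")
  f_stat <- sum(p^2) / (2 * sum(s2))
  structure(
    list(statistic = f_stat, df = c(10, 5),
         p.value = stats::pf(f_stat, 10, 5, lower.tail = FALSE),
         diffs = p, s2 = s2),
    class = "ftest_5x2"
  )
}

#' @export
print.ftest_5x2 <- function(x, ...) {
  cat(sprintf("Combined 5x2-fold CV F-test: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p.value))
  invisible(x)
}

#' Run the 5x2 CV comparison of two model configurations
#'
#' Orchestrates five replications of patient-level stratified 2-fold CV:
#' in each replication patients are split in half (stratified by label);
#' each half serves once as training set and once as test set, both model
#' configurations are trained on the same folds, and test accuracy is
#' recorded. The resulting 5 x 2 accuracy matrices feed
#' [five_by_two_cv_ftest()].
#'
#' @param x_a,x_b Montage arrays (`h x w x n`) for input formats A and B,
#'   aligned observation-for-observation.
#' @param labels Case/non-case label per observation.
#' @param patient_ids Patient id per observation (splits are by patient).
#' @param config_a,config_b Model configurations ([dcnn_config()]).
#' @param seed Integer seed for the five replications.
#' @return List: `ftest` (`ftest_5x2`), `acc_a`, `acc_b` (5 x 2 matrices).
#' @export
five_by_two_compare <- function(x_a, x_b, labels, patient_ids,
                                config_a = dcnn_config(), config_b = config_a,
                                seed = 1) {
  y <- as_case(labels)
  pts <- unique(patient_ids)
  plab <- vapply(pts, function(p) any(y[patient_ids == p]), logical(1))
  acc_a <- acc_b <- matrix(NA_real_, 5, 2)
  rep_seeds <- with_seed(seed, sample.int(2^31 - 2, 5))
  for (i in 1:5) {
    half <- with_seed(rep_seeds[i], {
      g <- integer(length(pts))
      for (lv in c(TRUE, FALSE)) {
        ids <- sample(which(plab == lv))
        g[ids] <- rep_len(1:2, length(ids))
      }
      g
    })
    for (j in 1:2) {
      test_p <- pts[half == j]
      tr <- !(patient_ids %in% test_p)
      for (m in c("a", "b")) {
        xx <- if (m == "a") x_a else x_b
        cfg <- if (m == "a") config_a else config_b
        cfg$seed <- rep_seeds[i] %% 10000 + j
        fit <- dcnn_fit(index_images(xx, tr), y[tr], config = cfg)
        pr <- predict(fit, index_images(xx, !tr))
        acc <- threshold_metrics(y[!tr], pr[, "case"] >= 0.5)$accuracy
        if (m == "a") acc_a[i, j] <- acc else acc_b[i, j] <- acc
      }
    }
  }
  list(ftest = five_by_two_cv_ftest(acc_a, acc_b), acc_a = acc_a, acc_b = acc_b)
}
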