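# Discrimination metrics. Labels are coerced to logical "is case"; accepted
# codings: logical, 0/1 numeric, or character/factor with "case"/"CASE"
# marking positives.

as_case <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) em_stop("em_input_error", "numeric labels must be 0/1")
    return(labels == 1)
  }
  l <- toupper(as.character(labels))
  if (!all(l %in% c("CASE", "NON_CASE", "NON-CASE", "NONCASE")))
    em_stop("em_input_error", "labels must code case vs non-case")
  l == "CASE"
}

#' Confusion-matrix metrics at a fixed decision threshold
#'
#' From the confusion counts: accuracy = (TP+TN)/n, PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), F1 = 2TP/(2TP+FP+FN). A zero denominator yields `NA`
#' (undefined), which fold summaries exclude with a warning.
#'
#' @param labels True labels (case/non-case in any accepted coding).
#' @param predicted Predicted labels, same length and coding.
#' @return List with `accuracy`, `f1`, `ppv`, `npv` (each in `[0,1]` or `NA`).
#' @export
threshold_metrics <- function(labels, predicted) {
  y <- as_case(labels); p <- as_case(predicted)
  if (length(y) == 0L || length(y) != length(p))
    em_stop("em_input_error", "labels and predictions must be non-empty, equal length")
  tp <- sum(y & p); fp <- sum(!y & p); tn <- sum(!y & !p); fn <- sum(y & !p)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = (tp + tn) / length(y),
       f1 = safe(2 * tp, 2 * tp + fp + fn),
       ppv = safe(tp, tp + fp),
       npv = safe(tn, tn + fn))
}

#' ROC and precision-recall curves with areas
#'
#' AUROC is the trapezoidal area under the full ROC curve, equal to the
#' Mann-Whitney pairwise statistic with ties counted one half. AUPRC is
#' average precision: the sum of precision times the recall increment at
#' each distinct score threshold (the standard estimator for imbalanced
#' screening data; no interpolation).
#'
#' @param labels True labels (both classes must be present).
#' @param scores Case probability or score per observation (higher = more
#'   case-like).
#' @return List of class `curve_metrics`: `auroc`, `auprc`, `roc`
#'   (data.frame threshold/fpr/tpr), `pr` (data.frame threshold/recall/
#'   precision).
#' @export
curve_metrics <- function(labels, scores) {
  y <- as_case(labels)
  stopifnot(length(y) == length(scores))
  if (all(y) || all(!y))
    em_stop("em_undefined_curve_error", "both classes required for ROC/PR curves")
  n_pos <- sum(y); n_neg <- sum(!y)

  # AUROC: rank form of the Mann-Whitney U statistic (ties -> midranks)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # curve points at distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp <- !duplicated(ss)
  cum_tp <- cumsum(ys); cum_fp <- cumsum(!ys)
  last <- which(c(grp[-1], TRUE))  # last index of each tied block
  tp <- cum_tp[last]; fp <- cum_fp[last]
  roc <- data.frame(threshold = ss[last], fpr = fp / n_neg, tpr = tp / n_pos)
  prec <- tp / (tp + fp); rec <- tp / n_pos
  pr <- data.frame(threshold = ss[last], recall = rec, precision = prec)
  auprc <- sum(diff(c(0, rec)) * prec)

  structure(list(auroc = auroc, auprc = auprc, roc = roc, pr = pr),
            class = "curve_metrics")
}

#' Compute all per-fold metrics from probabilities
#'
#' Thresholded metrics use the argmax rule (case iff p_case >= 0.5).
#'
#' @param labels True labels.
#' @param p_case Predicted case probabilities.
#' @param fold Fold identifier stored alongside.
#' @return One-row data.frame: fold, auroc, auprc, f1, accuracy, ppv, npv.
#' @export
fold_metrics <- function(labels, p_case, fold = NA) {
  cm <- curve_metrics(labels, p_case)
  tm <- threshold_metrics(labels, p_case >= 0.5)
  data.frame(fold = fold, auroc = cm$auroc, auprc = cm$auprc, f1 = tm$f1,
             accuracy = tm$accuracy, ppv = tm$ppv, npv = tm$npv)
}

#' Aggregate fold metrics as mean +/- SD
#'
#' Sample standard deviation (n-1). Undefined (NA) fold values are excluded
#' from the aggregate with a warning; a metric undefined in every fold stays
#' undefined.
#'
#' @param folds Data.frame of per-fold metrics (as from [fold_metrics()]),
#'   or a list of such rows.
#' @return Data.frame of class `cv_summary`: metric, mean, sd, n_folds,
#'   n_defined, rendered ("mean ± sd" to 2 decimals).
#' @export
summarize_folds <- function(folds) {
  if (is.list(folds) && !is.data.frame(folds)) folds <- do.call(rbind, folds)
  if (nrow(folds) < 2) em_stop("em_input_error", "need >= 2 folds to summarize")
  metrics <- setdiff(names(folds), "fold")
  out <- lapply(metrics, function(m) {
    v <- folds[[m]]
    def <- !is.na(v)
    if (any(!def))
      em_warn("%s undefined in %d of %d folds; mean over the remaining folds",
              m, sum(!def), length(v))
    mu <- if (any(def)) mean(v[def]) else NA_real_
    sd_ <- if (sum(def) >= 2) stats::sd(v[def]) else NA_real_
    data.frame(metric = m, mean = mu, sd = sd_, n_folds = length(v),
               n_defined = sum(def),
               rendered = if (is.na(mu)) "undefined"
                          else sprintf("%.2f ± %.2f", mu, if (is.na(sd_)) 0 else sd_))
  })
  structure(do.call(rbind, out), class = c("cv_summary", "data.frame"))
}
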