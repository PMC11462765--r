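# Patient-level train/validation/test splitting. All montages of a patient
# inherit the patient's role, so no patient's studies ever straddle roles.

# Largest-remainder apportionment of role totals across label strata,
# constrained so rows sum to the stratum sizes and columns to the role
# totals (controlled rounding of the n_c * n_r / n quota matrix).
allocate_stratified <- function(class_n, role_n) {
  n <- sum(class_n)
  stopifnot(sum(role_n) == n)
  q <- outer(class_n, role_n) / n
  a <- floor(q)
  frac <- q - a
  repeat {
    col_def <- role_n - colSums(a)
    row_def <- class_n - rowSums(a)
    if (all(col_def == 0)) break
    best <- -Inf; bi <- bj <- NA
    for (i in seq_along(class_n)) for (j in seq_along(role_n)) {
      if (row_def[i] > 0 && col_def[j] > 0 && frac[i, j] > best) {
        best <- frac[i, j]; bi <- i; bj <- j
      }
    }
    a[bi, bj] <- a[bi, bj] + 1
    frac[bi, bj] <- -Inf
  }
  a
}

#' Patient-level stratified cross-validation splits
#'
#' Generates `n_folds` repeated stratified random splits of patients into
#' train/validation/test at the given ratios (Monte-Carlo CV with holdout
#' subsets, the default), or classic grouped k-fold splits. Role counts use
#' the floor rule: train gets `floor(n * r_train)`, the remainder is divided
#' val-then-test. Stratification keeps the case fraction within one patient
#' per role.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param labels Class label per patient (same length; any two-level coding).
#' @param n_folds Number of folds/resamples (default 10).
#' @param ratios Train/val/test percentages summing to 100 (default 70:15:15).
#' @param seed Integer seed.
#' @param mode `"montecarlo"` (repeated resampling, default) or `"kfold"`
#'   (grouped k-fold: test = fold i, validation = the next fold, train =
#'   the rest).
#' @return An object of class `split_plan`: list of folds, each a named
#'   character vector mapping patient id to `"train"`, `"val"`, or `"test"`.
#' @export
make_patient_splits <- function(patient_ids, labels, n_folds = 10,
                                ratios = c(70, 15, 15), seed = 1,
                                mode = c("montecarlo", "kfold")) {
  mode <- match.arg(mode)
  if (anyDuplicated(patient_ids))
    em_stop("em_input_error", "patient_ids must be unique")
  if (length(labels) != length(patient_ids))
    em_stop("em_input_error", "one label per patient required")
  if (abs(sum(ratios) - 100) > 1e-9)
    em_stop("em_config_error", "ratios must sum to 100")
  n <- length(patient_ids)
  if (n < 3) em_stop("em_input_error", "fewer patients than roles")
  labels <- as.character(labels)

  folds <- with_seed(seed, {
    if (mode == "kfold") {
      groups <- integer(n)
      for (lv in unique(labels)) {
        ids <- sample(which(labels == lv))
        groups[ids] <- rep_len(seq_len(n_folds), length(ids))
      }
      lapply(seq_len(n_folds), function(k) {
        val_g <- k %% n_folds + 1
        role <- ifelse(groups == k, "test", ifelse(groups == val_g, "val", "train"))
        stats::setNames(role, patient_ids)
      })
    } else {
      n_train <- floor(n * ratios[1] / 100)
      rem <- n - n_train
      n_val <- floor(rem * ratios[2] / (ratios[2] + ratios[3]))
      n_test <- rem - n_val
      class_n <- table(labels)
      lapply(seq_len(n_folds), function(k) {
        a <- allocate_stratified(as.integer(class_n), c(n_train, n_val, n_test))
        role <- character(n)
        for (ci in seq_along(class_n)) {
          ids <- sample(which(labels == names(class_n)[ci]))
          role[ids] <- rep(c("train", "val", "test"), times = a[ci, ])
        }
        stats::setNames(role, patient_ids)
      })
    }
  })
  structure(list(folds = folds, mode = mode, n_folds = n_folds,
                 ratios = ratios, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- table(x$folds[[1]])
  cat(sprintf("<split_plan> %d %s folds (%s), fold 1: %s\n",
              x$n_folds, x$mode, paste(x$ratios, collapse = ":"),
              paste(names(sizes), sizes, sep = "=", collapse = " ")))
  invisible(x)
}
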