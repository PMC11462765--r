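# End-to-end orchestration: clips -> QC -> montages -> labels/subsets ->
# patient-level CV training -> metrics -> optional montage-format comparison.

#' Build a labeled montage registry from a cohort
#'
#' Validates every clip, extracts the ECG-gated montage, standardizes it,
#' optionally downscales to a reduced working resolution, and attaches the
#' survivor label and cardiomyopathy index date needed for timing subsets.
#' Clips failing QC are reported, not errored.
#'
#' @param cohort Cohort list: `patients`, `echoes`, and `clips` (named list
#'   of [cine_clip()] by study id), as produced by
#'   [generate_phantom_cohort()] or assembled from [read_cohort()] +
#'   [read_dicom_clip()].
#' @param montage_type 1 or 2.
#' @param target_dims Standardized dimensions, `c(width, height)`.
#' @param reduce_to Optional `c(width, height)` working resolution applied
#'   after standardization (reduced-resolution mode).
#' @param at_dx_days At-diagnosis window passed to subset filtering later.
#' @return List: `registry` (data.frame incl. `label`, `cm_dx_date`),
#'   `images` (`h x w x n` array aligned with registry rows), `skipped`
#'   (data.frame of clip_id and QC reasons).
#' @export
build_montage_set <- function(cohort, montage_type = 1,
                              target_dims = c(1200, 900), reduce_to = NULL,
                              at_dx_days = 0) {
  labels <- classify_cohort(cohort)
  keep <- labels$label != "INDETERMINATE"
  labels <- labels[keep, , drop = FALSE]
  registry <- montage_registry()
  images <- list()
  skipped <- list()
  for (sid in names(cohort$clips)) {
    clip <- cohort$clips[[sid]]
    li <- match(clip$patient_id, labels$patient_id)
    if (is.na(li)) next  # indeterminate survivor: excluded from modeling
    qc <- validate_clip(clip, montage_type = montage_type)
    if (!qc$usable) {
      skipped[[length(skipped) + 1]] <- data.frame(
        clip_id = clip$clip_id, reasons = paste(qc$reasons, collapse = ";"))
      next
    }
    m <- montage_from_clip(clip, montage_type, target_dims = target_dims)
    img <- m$image
    if (!is.null(reduce_to)) img <- clamp8(resize_gray(img, reduce_to[2], reduce_to[1]))
    erow <- cohort$echoes[cohort$echoes$study_id == sid, ]
    registry <- register_montage(registry, m,
                                 echo_date = if (nrow(erow)) erow$echo_date[1] else as.Date(NA),
                                 label = labels$label[li])
    images[[length(images) + 1]] <- img
  }
  if (length(images) == 0L)
    em_stop("em_empty_subset_error", "no usable montages could be built")
  registry$cm_dx_date <- labels$cm_dx_date[match(registry$patient_id, labels$patient_id)]
  list(registry = registry,
       images = simplify2array(images),
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Patient-level cross-validated training and evaluation
#'
#' Runs the full CV loop: for each fold of the split plan, trains the
#' classifier on the training patients' montages (validation patients drive
#' early stopping), predicts the held-out test patients, and computes the
#' fold's discrimination metrics.
#'
#' @param images `h x w x n` montage array.
#' @param labels Montage-level labels (case/non-case).
#' @param patient_ids Patient id per montage.
#' @param config A [dcnn_config()].
#' @param n_folds,ratios,seed,mode Passed to [make_patient_splits()].
#' @return List of class `cv_result`: `plan`, `metrics` (per-fold
#'   data.frame), `summary` ([summarize_folds()]), `predictions`, `curves`
#'   (per-fold ROC/PR point data).
#' @export
cross_validate <- function(images, labels, patient_ids, config = dcnn_config(),
                           n_folds = 10, ratios = c(70, 15, 15), seed = 1,
                           mode = "montecarlo") {
  y <- as_case(labels)
  pts <- unique(patient_ids)
  plab <- vapply(pts, function(p) any(y[patient_ids == p]), logical(1))
  plan <- make_patient_splits(pts, ifelse(plab, "CASE", "NON_CASE"),
                              n_folds = n_folds, ratios = ratios, seed = seed,
                              mode = mode)
  metrics <- NULL; preds <- NULL; curves <- list()
  for (k in seq_len(n_folds)) {
    role <- plan$folds[[k]][patient_ids]
    cfg <- config
    cfg$seed <- config$seed + k
    fit <- dcnn_fit(index_images(images, role == "train"), y[role == "train"],
                    index_images(images, role == "val"), y[role == "val"],
                    config = cfg)
    p <- predict(fit, index_images(images, role == "test"))
    yk <- y[role == "test"]
    metrics <- rbind(metrics, fold_metrics(yk, p[, "case"], fold = k))
    cm <- curve_metrics(yk, p[, "case"])
    curves[[k]] <- list(roc = cm$roc, pr = cm$pr)
    preds <- rbind(preds, data.frame(fold = k,
                                     patient_id = patient_ids[role == "test"],
                                     label = yk, p_case = p[, "case"]))
  }
  structure(list(plan = plan, metrics = metrics, summary = summarize_folds(metrics),
                 predictions = preds, curves = curves),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", nrow(x$metrics)))
  print(as.data.frame(x$summary)[, c("metric", "rendered")], row.names = FALSE)
  invisible(x)
}

default_experiment_config <- function() {
  list(
    montage_type = 1,
    subset = "AT_DX_AND_PRE",
    at_dx_days = 0,
    target_dims = c(1200, 900),
    reduce_to = NULL,
    model = list(),
    cv = list(n_folds = 10, ratios = c(70, 15, 15), seed = 1, mode = "montecarlo"),
    compare = FALSE,
    seed = 1
  )
}

#' Read an experiment configuration file (YAML or JSON)
#' @param path Config file path; format chosen by extension.
#' @return Configuration list for [run_experiment()].
#' @export
read_experiment_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      em_stop("em_config_error", "yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run a full experiment from a single configuration
#'
#' Orchestrates simulation or loading of a cohort, montage construction,
#' case-subset filtering, patient-level cross-validated training and
#' evaluation, and (optionally) the combined 5x2 CV F-test comparing the
#' single-cycle and two-cycle montage formats. Any stage failure propagates
#' with its stage name prefixed.
#'
#' @param config Configuration list (see Details) or a path readable by
#'   [read_experiment_config()]. Recognized fields: `cohort` (in-memory
#'   cohort list or a directory for [read_cohort()] with a `clips/`
#'   subdirectory of DICOMs), `simulate` (arguments to
#'   [generate_phantom_cohort()], used when no cohort is given),
#'   `montage_type`, `subset`, `at_dx_days`, `target_dims`, `reduce_to`,
#'   `model` (arguments to [dcnn_config()]), `cv` (`n_folds`, `ratios`,
#'   `seed`, `mode`), `compare` (run the 5x2 F-test of Type 1 vs Type 2),
#'   and `out_dir`.
#' @return A results bundle: montage `counts` per class, per-fold `metrics`,
#'   `summary`, `curves`, optional `ftest`, and a `manifest` echoing seeds
#'   and configuration. Written to `out_dir` when given.
#' @export
run_experiment <- function(config = list()) {
  if (is.character(config)) config <- read_experiment_config(config)
  cfg <- utils::modifyList(default_experiment_config(), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$cohort)) {
      if (is.character(cfg$cohort)) {
        co <- read_cohort(cfg$cohort)
        clip_files <- list.files(file.path(cfg$cohort, "clips"),
                                 pattern = "\\.dcm$", full.names = TRUE)
        co$clips <- stats::setNames(lapply(clip_files, read_dicom_clip),
                                    sub("\\.dcm$", "", basename(clip_files)))
        co
      } else cfg$cohort
    } else if (!is.null(cfg$simulate)) {
      do.call(generate_phantom_cohort, cfg$simulate)
    } else {
      em_stop("em_config_error", "config needs either `cohort` or `simulate`")
    }
  })

  build_one <- function(type) stage("montage", {
    ms <- build_montage_set(cohort, type, target_dims = cfg$target_dims,
                            reduce_to = cfg$reduce_to, at_dx_days = cfg$at_dx_days)
    sel <- select_case_subset(ms$registry, cfg$subset, at_dx_days = cfg$at_dx_days)
    keep <- rownames(ms$registry) %in% rownames(sel)
    if (!any(keep & ms$registry$label == "CASE") || !any(keep & ms$registry$label == "NON_CASE"))
      em_stop("em_empty_subset_error",
              "subset %s leaves no usable case/non-case montages", cfg$subset)
    ii <- index_images(ms$images, keep)
    dim(ii) <- dim(ii)[c(1, 2, 4)]
    list(registry = ms$registry[keep, , drop = FALSE],
         images = ii,
         skipped = ms$skipped)
  })

  ms <- build_one(cfg$montage_type)
  counts <- table(factor(ms$registry$label, levels = c("CASE", "NON_CASE")))

  model_cfg <- stage("model", {
    margs <- cfg$model
    if (is.null(margs$input_dims))
      margs$input_dims <- if (!is.null(cfg$reduce_to)) cfg$reduce_to else cfg$target_dims
    do.call(dcnn_config, margs)
  })

  cv <- stage("train", {
    cross_validate(ms$images, ms$registry$label, ms$registry$patient_id,
                   config = model_cfg, n_folds = cfg$cv$n_folds,
                   ratios = cfg$cv$ratios, seed = cfg$cv$seed,
                   mode = cfg$cv$mode %||% "montecarlo")
  })

  ftest <- NULL
  if (isTRUE(cfg$compare)) {
    ftest <- stage("compare", {
      ms2 <- build_one(if (cfg$montage_type == 1) 2 else 1)
      shared <- intersect(ms$registry$study_id, ms2$registry$study_id)
      i1 <- match(shared, ms$registry$study_id)
      i2 <- match(shared, ms2$registry$study_id)
      five_by_two_compare(index_images(ms$images, i1), index_images(ms2$images, i2),
                          ms$registry$label[i1], ms$registry$patient_id[i1],
                          config_a = model_cfg, config_b = model_cfg,
                          seed = cfg$cv$seed)
    })
  }

  manifest <- list(
    run_id = sprintf("%s-%08x", format(Sys.time(), "%Y%m%d%H%M%S"),
                     as.integer(cfg$cv$seed) * 2654435L %% .Machine$integer.max),
    seed = cfg$seed, cv_seed = cfg$cv$seed,
    montage_type = cfg$montage_type, subset = cfg$subset,
    counts = list(cm_pos = unname(counts["CASE"]), cm_neg = unname(counts["NON_CASE"])),
    n_skipped = if (is.null(ms$skipped)) 0L else nrow(ms$skipped),
    config = cfg[setdiff(names(cfg), c("cohort"))]
  )
  message(sprintf("subset %s: CM+ %d / CM- %d montages (type %d)",
                  cfg$subset, counts["CASE"], counts["NON_CASE"], cfg$montage_type))

  bundle <- list(registry = ms$registry, counts = counts, metrics = cv$metrics,
                 summary = cv$summary, predictions = cv$predictions,
                 curves = cv$curves, ftest = ftest, manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    run_dir <- file.path(cfg$out_dir, manifest$run_id)
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cv$metrics, file.path(run_dir, "fold_metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cv$summary), file.path(run_dir, "summary.csv"),
                     row.names = FALSE)
    roc_all <- do.call(rbind, lapply(seq_along(cv$curves), function(k)
      cbind(fold = k, cv$curves[[k]]$roc)))
    pr_all <- do.call(rbind, lapply(seq_along(cv$curves), function(k)
      cbind(fold = k, cv$curves[[k]]$pr)))
    utils::write.csv(roc_all, file.path(run_dir, "roc_points.csv"), row.names = FALSE)
    utils::write.csv(pr_all, file.path(run_dir, "pr_points.csv"), row.names = FALSE)
    if (!is.null(ftest))
      jsonlite::write_json(list(F = ftest$ftest$statistic, df = ftest$ftest$df,
                                p = ftest$ftest$p.value),
                           file.path(run_dir, "ftest.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    bundle$run_dir <- run_dir
  }
  bundle
}
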