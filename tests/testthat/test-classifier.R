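test_that("patient splits hit the 70:15:15 counts and stay stratified", {
  ids <- sprintf("P%03d", 1:100)
  labs <- rep(c("CASE", "NON_CASE"), c(40, 60))
  plan <- make_patient_splits(ids, labs, n_folds = 10, seed = 1)
  for (fold in plan$folds) {
    expect_equal(sum(fold == "train"), 70)
    expect_equal(sum(fold == "val"), 15)
    expect_equal(sum(fold == "test"), 15)
    # stratification within one patient per role
    for (role in c("train", "val", "test")) {
      frac <- sum(labs[fold == role] == "CASE")
      expect_lte(abs(frac - 0.4 * sum(fold == role)), 1)
    }
  }
})

test_that("split rounding gives train the floor, remainder val-then-test", {
  plan <- make_patient_splits(sprintf("P%02d", 1:20),
                              rep(c("CASE", "NON_CASE"), 10), n_folds = 2, seed = 2)
  expect_equal(as.integer(table(plan$folds[[1]])[c("train", "val", "test")]),
               c(14L, 3L, 3L))
})

test_that("every fold partitions the patients with no leakage, across seeds", {
  ids <- sprintf("P%03d", 1:100)
  labs <- rep(c("CASE", "NON_CASE"), c(40, 60))
  for (seed in 1:5) {
    plan <- make_patient_splits(ids, labs, n_folds = 10, seed = seed)
    for (fold in plan$folds) {
      expect_setequal(names(fold), ids)          # union = all patients
      expect_equal(anyDuplicated(names(fold)), 0)  # each patient one role
      expect_true(all(fold %in% c("train", "val", "test")))
    }
  }
})

test_that("montage-level roles inherit the patient role (adversarial many-study case)", {
  ids <- sprintf("P%02d", 1:12)
  labs <- rep(c("CASE", "NON_CASE"), 6)
  plan <- make_patient_splits(ids, labs, n_folds = 5, seed = 3)
  # a patient with many studies gets the same role for every study
  study_patients <- rep(ids, times = sample(1:6, 12, replace = TRUE))
  for (fold in plan$folds) {
    study_roles <- fold[study_patients]
    for (p in ids)
      expect_length(unique(study_roles[study_patients == p]), 1L)
  }
})

test_that("grouped k-fold mode also partitions cleanly", {
  ids <- sprintf("P%03d", 1:30)
  labs <- rep(c("CASE", "NON_CASE"), 15)
  plan <- make_patient_splits(ids, labs, n_folds = 5, seed = 4, mode = "kfold")
  test_sets <- lapply(plan$folds, function(f) names(f)[f == "test"])
  expect_setequal(unlist(test_sets), ids)  # every patient tested once
  expect_equal(sum(lengths(test_sets)), 30)
  for (fold in plan$folds) expect_setequal(names(fold), ids)
})

test_that("bad split requests are rejected", {
  expect_error(make_patient_splits(c("a", "b", "c"), c(1, 0, 1), ratios = c(80, 15, 15)),
               class = "em_config_error")
  expect_error(make_patient_splits(c("a", "b"), c(1, 0)), class = "em_input_error")
  expect_error(make_patient_splits(c("a", "a", "b"), c(1, 0, 1)),
               class = "em_input_error")
})

test_that("parameter count matches closed-form layer arithmetic", {
  hand_count <- function(width, height, blocks, fc) {
    h <- height; w <- width; cin <- 1; total <- 0
    for (b in blocks) {
      f <- b[1]; k <- b[2]; s <- b[3]; p <- b[4]
      total <- total + (k * k * cin + 1) * f + 2 * f  # conv + bias + BN scale/shift
      h <- floor((h + (k - 1) - k) / s + 1) %/% p
      w <- floor((w + (k - 1) - k) / s + 1) %/% p
      cin <- f
    }
    total + (h * w * cin + 1) * fc + (fc + 1) * 2
  }
  set.seed(17)
  for (i in 1:20) {
    blocks <- list(c(sample(2:12, 1), 3, 1, sample(2:3, 1)),
                   c(sample(2:24, 1), sample(c(3, 5), 1), 1, 2))
    wd <- sample(40:200, 1); ht <- sample(40:200, 1)
    fc <- sample(4:64, 1)
    cfg <- dcnn_config(input_dims = c(wd, ht), blocks = blocks, fc_units = fc)
    expect_equal(dcnn_param_count(cfg), hand_count(wd, ht, blocks, fc))
  }
})

test_that("the architecture is fixed at two principal blocks", {
  expect_error(dcnn_config(blocks = list(c(8, 3, 1, 2), c(16, 3, 1, 2), c(32, 3, 1, 2))),
               class = "em_config_error")
  expect_error(dcnn_config(input_dims = c(4, 4),
                           blocks = list(c(8, 3, 1, 4), c(16, 3, 1, 4))),
               class = "em_config_error")  # collapses below 1 pixel
  expect_error(dcnn_config(blocks = list(c(8, 4, 1, 2), c(16, 3, 1, 2))),
               class = "em_config_error")  # even kernel
})

test_that("softmax output is a probability pair, deterministic at inference", {
  cfg <- dcnn_config(input_dims = c(32, 24), fc_units = 8, seed = 5)
  model <- dcnn_build(cfg)
  set.seed(6)
  x <- array(runif(24 * 32 * 5, 0, 255), dim = c(24, 32, 5))
  x[, , 5] <- x[, , 1]  # duplicate montage
  p <- predict(model, x)
  expect_false(anyNA(p))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[5, ], p[1, ])  # duplicates get identical probabilities
})

test_that("training reduces loss on linearly separable toy montages", {
  set.seed(8)
  n <- 24
  x <- array(runif(24 * 32 * n, 0, 40), dim = c(24, 32, n))
  y <- rep(c("CASE", "NON_CASE"), n / 2)
  x[, , y == "CASE"] <- x[, , y == "CASE"] + 150  # bright vs dark tiles
  cfg <- dcnn_config(input_dims = c(32, 24), fc_units = 8, epochs = 5,
                     batch_size = 8, seed = 9)
  fit <- dcnn_fit(x, y, config = cfg)
  expect_lt(fit$history$train_loss[nrow(fit$history)], fit$history$train_loss[1])
  expect_true(fit$trained)
})

test_that("the same seed reproduces the first-epoch loss", {
  set.seed(10)
  x <- array(runif(24 * 32 * 16, 0, 255), dim = c(24, 32, 16))
  y <- rep(c("CASE", "NON_CASE"), 8)
  cfg <- dcnn_config(input_dims = c(32, 24), fc_units = 8, epochs = 2,
                     batch_size = 8, seed = 11)
  f1 <- dcnn_fit(x, y, config = cfg)
  f2 <- dcnn_fit(x, y, config = cfg)
  expect_equal(f1$history$train_loss[1], f2$history$train_loss[1],
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  x <- array(runif(24 * 32 * 8), dim = c(24, 32, 8))
  cfg <- dcnn_config(input_dims = c(32, 24), fc_units = 4, epochs = 1)
  expect_error(dcnn_fit(x, rep("CASE", 8), config = cfg),
               class = "em_degenerate_data_error")
  model <- dcnn_build(cfg)
  bad <- array(runif(10 * 10 * 2), dim = c(10, 10, 2))
  expect_error(predict(model, bad), class = "em_input_error")
})

test_that("learning on phantom montages beats a label-permuted control", {
  # test sets must be large enough for the permuted-control sigma to be
  # informative: 100 patients with 20 held out per fold
  co <- generate_phantom_cohort(100, 0.4, echoes_per_patient = c(1, 1), seed = 21,
                                clip_params = list(image_dims = c(100, 76),
                                                   n_cycles = 2))
  ms <- build_montage_set(co, 1, reduce_to = c(100, 76))
  y <- ms$registry$label
  cfg <- dcnn_config(input_dims = c(100, 76), blocks = list(c(6, 3, 1, 2), c(12, 3, 1, 2)),
                     fc_units = 16, epochs = 8, patience = 3, batch_size = 8, seed = 30)
  cv <- suppressWarnings(
    cross_validate(ms$images, y, ms$registry$patient_id, cfg,
                   n_folds = 3, ratios = c(60, 20, 20), seed = 30))
  set.seed(31)
  perm_auroc <- replicate(5, {
    yp <- sample(y)
    cvp <- suppressWarnings(
      cross_validate(ms$images, yp, ms$registry$patient_id, cfg,
                     n_folds = 2, ratios = c(60, 20, 20), seed = 32))
    mean(cvp$metrics$auroc)
  })
  expect_gt(mean(cv$metrics$auroc), 0.5 + 3 * sd(perm_auroc))
})
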