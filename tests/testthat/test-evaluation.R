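lesion_classes <- c("nevus", "melanoma", "bcc")

test_that("confusion matrix counts truth rows against prediction columns", {
  # perfect predictions: diagonal matrix, accuracy 1
  truth <- rep(lesion_classes, each = 14)
  cm <- confusion_matrix(truth, truth, lesion_classes)
  expect_equal(unname(diag(cm)), c(14L, 14L, 14L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_equal(metrics_from_cm(cm)$top1_accuracy, 1)
  # three-sample enumeration
  cm2 <- confusion_matrix(c("nevus", "nevus", "melanoma"),
                          c("nevus", "melanoma", "melanoma"), lesion_classes)
  expect_equal(unclass(cm2),
               matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L), 3, 3),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(c("nevus"), c("wart"), lesion_classes),
               "unknown")
  expect_error(confusion_matrix(c("nevus"), c("nevus", "bcc"), lesion_classes),
               "lengths")
})

test_that("per-class TP/FN/FP/TN decomposition matches a per-sample recount", {
  cm <- as_confusion_matrix(matrix(c(12, 1, 1, 2, 10, 2, 0, 3, 11),
                                   3, 3, byrow = TRUE), lesion_classes)
  oracle <- brute_force_metrics(unclass(cm))
  rep <- metrics_from_cm(cm)
  # melanoma row: TP 10, FN 4, FP 4, TN 24
  expect_equal(rep$per_class$sensitivity[2], 10 / 14)
  expect_equal(rep$per_class$specificity[2], 24 / 28)
  expect_equal(rep$per_class$precision[2], 10 / 14)
  expect_equal(as.matrix(rep$per_class[2:5]), oracle$per_class,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rep$top1_accuracy, oracle$accuracy)
})

test_that("metrics agree with the brute-force oracle on 1000 random matrices", {
  set.seed(2024)
  worst <- 0
  for (i in 1:1000) {
    C <- sample(2:4, 1)
    counts <- matrix(rpois(C * C, 3), C, C)
    diag(counts) <- diag(counts) + 1 # every class needs a true sample
    cm <- as_confusion_matrix(counts)
    rep <- metrics_from_cm(cm)
    oracle <- brute_force_metrics(counts)
    worst <- max(worst,
                 max(abs(as.matrix(rep$per_class[2:5]) - oracle$per_class)),
                 abs(rep$top1_accuracy - oracle$accuracy))
  }
  expect_lt(worst, 1e-12)
})

test_that("F1 identities reproduce the published per-class table rows", {
  # harmonic mean of printed SE and P, rounded to 2 d.p.
  expect_equal(round(f1_score(0.79, 0.92), 2), 0.85) # 2D-CNN cube, melanoma
  expect_equal(round(f1_score(0.07, 0.25), 2), 0.11) # 2D-CNN RGB, nevus
  expect_equal(round(f1_score(0.43, 0.75), 2), 0.55) # 3D VGG RGB, melanoma
  expect_equal(round(f1_score(0.89, 0.93), 2), 0.91) # 2D-CNN, malignant/benign
  # zero-division conventions
  expect_equal(f1_score(0, 0), 0)
})

test_that("every report satisfies the F1 harmonic-mean identity", {
  set.seed(31)
  for (i in 1:50) {
    counts <- matrix(rpois(9, 4), 3, 3)
    diag(counts) <- diag(counts) + 1
    rep <- metrics_from_cm(as_confusion_matrix(counts, lesion_classes))
    with(rep$per_class,
         expect_equal(f1, f1_score(sensitivity, precision), tolerance = 1e-12))
  }
})

test_that("malignant collapse merges blocks and cannot lose samples", {
  cm <- as_confusion_matrix(matrix(c(12, 1, 1, 2, 10, 2, 0, 3, 11),
                                   3, 3, byrow = TRUE), lesion_classes)
  b <- collapse_malignant(cm)
  expect_equal(unclass(b), matrix(c(12L, 2L, 2L, 26L), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(sum(b), sum(cm))
  # perfect classifier stays perfect; all-benign mass leaves malignant empty
  expect_equal(sum(diag(collapse_malignant(
    as_confusion_matrix(diag(c(5L, 6L, 7L)), lesion_classes)))), 18L)
  nb <- as_confusion_matrix(matrix(c(4, 3, 2, 0, 0, 0, 0, 0, 0), 3, 3,
                                   byrow = TRUE), lesion_classes)
  expect_equal(unname(unclass(collapse_malignant(nb))[2, ]), c(0L, 0L))
  # merging classes can only help accuracy
  set.seed(77)
  for (i in 1:25) {
    counts <- matrix(rpois(9, 4), 3, 3)
    diag(counts) <- diag(counts) + 1
    cm3 <- as_confusion_matrix(counts, lesion_classes)
    expect_gte(metrics_from_cm(collapse_malignant(cm3))$top1_accuracy,
               metrics_from_cm(cm3)$top1_accuracy)
  }
  expect_error(collapse_malignant(as_confusion_matrix(diag(3L))), "include")
})

test_that("saliency of a linear model is its folded absolute weights", {
  sp <- architecture_spec("lin", c(5, 5, 2), list(
    layer_spec("flatten"), layer_spec("softmax_output", units = 2L)), 2L)
  m <- build_model(sp, seed = 2)
  cube <- reflectance_cube(array(runif(50), c(5, 5, 2)), c(447, 671))
  sm <- saliency_map(m, cube, target_class = 2L)
  ref <- apply(array(abs(m$layers[[2]]$W[, 2]), c(5, 5, 2)), c(1, 2), max)
  expect_equal(sm$values, ref / max(ref), tolerance = 1e-12)
  expect_equal(max(sm$values), 1)
  # a zero-weight model yields an all-zero map (normalization skipped)
  m0 <- m
  m0$layers[[2]]$W[] <- 0
  expect_true(all(saliency_map(m0, cube, target_class = 1L)$values == 0))
})

test_that("a trained model attends to the lesion, not surrounding skin", {
  cfg <- sim_config(frame_shape = c(16, 16), separability_mode = "all_bands",
                    class_concentration_ranges = wide_gap_ranges(),
                    class_counts = c(nevus = 20, melanoma = 20, bcc = 20),
                    seed = 14)
  caps <- simulate_dataset(cfg)
  ds <- labeled_dataset(lapply(caps, calibrate), c("nevus", "melanoma", "bcc"))
  plan <- make_fold_plan(ds, 0.2, 2L, seed = 14)
  tc <- train_config(batch_size = 4L, learning_rate = 1e-3,
                     epochs_per_fold = 5L, seed = 14)
  fit <- train_cross_validated(spec_cnn2d(c(16, 16, 8), 3L), ds, plan, tc)
  # average over several melanoma test cubes (stochastic property)
  idx <- which(vapply(caps, `[[`, character(1), "true_label") == "melanoma")[1:8]
  ratio <- vapply(idx, function(i) {
    sm <- saliency_map(fit$model, ds$cubes[[i]])
    mask <- caps[[i]]$lesion_mask
    mean(sm$values[mask]) / mean(sm$values[!mask])
  }, numeric(1))
  expect_gt(mean(ratio), 1)
})
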