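test_that("2D CNN spec reproduces the published layer schedule and count", {
  spec <- spec_cnn2d(c(128, 128, 8), 3L)
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_equal(kinds, c(rep("conv2d", 6), "flatten", "softmax_output"))
  expect_equal(vapply(spec$layers[1:6], `[[`, numeric(1), "filters"),
               c(8, 8, 16, 16, 32, 32))
  expect_equal(vapply(spec$layers[1:6], `[[`, numeric(1), "stride"),
               c(1, 2, 1, 2, 1, 2))
  expect_equal(count_parameters(spec), 43123L)
  # RGB-subset variant: same layer list, 3 input channels
  spec3 <- spec_cnn2d(c(128, 128, 3), 3L)
  expect_equal(vapply(spec3$layers[1:6], `[[`, numeric(1), "filters"),
               c(8, 8, 16, 16, 32, 32))
  # shape propagation at a small input: flatten sees 2 x 2 x 32
  sp <- spec_cnn2d(c(16, 16, 1), 2L)
  expect_equal(count_parameters(sp),
               as.integer(3 * 3 * 1 * 8 + 8 + 3 * 3 * 8 * 8 + 8 +
                          3 * 3 * 8 * 16 + 16 + 3 * 3 * 16 * 16 + 16 +
                          3 * 3 * 16 * 32 + 32 + 3 * 3 * 32 * 32 + 32 +
                          (2 * 2 * 32) * 2 + 2))
})

test_that("3D VGG-16 spec has 13 convs, 5 pools, 3 dense and 256 in block 4", {
  spec <- spec_vgg16_3d(c(128, 128, 8, 1), 3L)
  kinds <- vapply(spec$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "conv3d"), 13L)
  expect_equal(sum(kinds == "maxpool3d"), 5L)
  expect_equal(sum(kinds %in% c("dense", "softmax_output")), 3L)
  filt <- vapply(spec$layers[kinds == "conv3d"], `[[`, numeric(1), "filters")
  expect_equal(filt, c(64, 64, 128, 128, 256, 256, 256, 256, 256, 256,
                       512, 512, 512))
  drops <- spec$layers[kinds == "dropout"]
  expect_length(drops, 2L)
  expect_true(all(vapply(drops, `[[`, numeric(1), "rate") == 0.5))
  expect_true(all(vapply(spec$layers[kinds == "conv3d"], `[[`,
                         character(1), "init") == "he_uniform"))
  # shapes propagate to a non-empty flatten on a small input
  expect_gt(count_parameters(spec_vgg16_3d(c(32, 32, 8, 1), 3L)), 0)
})

test_that("closed-form parameter counts match hand arithmetic", {
  # single conv2d(4, k3, s2, same) on (8,8,1): 40 params, flatten 4*4*4,
  # dense softmax(3): 195 params
  sp <- architecture_spec("hand", c(8, 8, 1), list(
    layer_spec("conv2d", filters = 4L, kernel = 3L, stride = 2L,
               activation = "relu"),
    layer_spec("flatten"),
    layer_spec("softmax_output", units = 3L)), 3L)
  expect_equal(count_parameters(sp), 235L)
  # no hidden layers: flat n-dim input into c classes
  sp2 <- architecture_spec("lin", c(4, 5, 2), list(
    layer_spec("flatten"), layer_spec("softmax_output", units = 3L)), 3L)
  expect_equal(count_parameters(sp2), 40L * 3L + 3L)
})

test_that("count_parameters equals the instantiated weight totals", {
  # both study architectures (the VGG at a desk-scale input geometry)
  m1 <- build_model(spec_cnn2d(c(128, 128, 8), 3L), seed = 1)
  expect_equal(m1$parameter_count, 43123)
  sv <- spec_vgg16_3d(c(32, 32, 8, 1), 3L)
  m2 <- build_model(sv, seed = 1)
  expect_equal(m2$parameter_count, count_parameters(sv))
  # actual array lengths, independent of the builder's own bookkeeping
  expect_equal(sum(vapply(m2$layers, function(l)
    length(l$W) + length(l$b), numeric(1))), count_parameters(sv))

  # 20 random small architectures, 2D and 3D
  set.seed(42)
  for (i in 1:20) {
    three_d <- i %% 2 == 0
    shape <- if (three_d) c(8, 8, 4, sample(1:3, 1)) else c(12, 12, sample(1:4, 1))
    layers <- list()
    for (j in seq_len(sample(1:3, 1))) {
      layers[[j]] <- layer_spec(if (three_d) "conv3d" else "conv2d",
                                filters = sample(2:6, 1),
                                kernel = sample(1:3, 1),
                                stride = sample(1:2, 1),
                                activation = "relu")
    }
    if (three_d && runif(1) < 0.5) {
      layers <- c(layers, list(layer_spec("maxpool3d")))
    }
    cc <- sample(2:4, 1)
    layers <- c(layers, list(layer_spec("flatten"),
                             layer_spec("softmax_output", units = cc)))
    spec <- architecture_spec(paste0("rand", i), shape, layers, cc)
    m <- build_model(spec, seed = i)
    expect_equal(m$parameter_count, count_parameters(spec),
                 info = paste("random spec", i))
  }
})

test_that("weighted categorical cross-entropy matches hand values", {
  expect_equal(weighted_categorical_cross_entropy(c(0, 1, 0), c(0.2, 0.5, 0.3)),
               -log(0.5), tolerance = 1e-12)
  expect_equal(round(weighted_categorical_cross_entropy(
    c(0, 1, 0), c(0.2, 0.5, 0.3)), 4), 0.6931)
  # weight 2 on the true class doubles the loss
  expect_equal(weighted_categorical_cross_entropy(
    c(0, 1, 0), c(0.2, 0.5, 0.3), c(1, 2, 1)), -2 * log(0.5))
  # batch averaging
  truth <- rbind(c(1, 0), c(0, 1))
  sc <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(weighted_categorical_cross_entropy(truth, sc),
               mean(-log(c(0.8, 0.6))))
  # near-perfect prediction stays below the epsilon-floor bound
  expect_lte(weighted_categorical_cross_entropy(c(1, 0, 0),
                                                c(1 - 2e-7, 1e-7, 1e-7)),
             -log(1 - 3e-7) + 1e-6)
  expect_error(weighted_categorical_cross_entropy(c(0, 1), c(0.9, 0.4)),
               "normalized")
})

test_that("softmax outputs of built models are normalized probabilities", {
  m <- build_model(spec_cnn2d(c(16, 16, 4), 3L), seed = 5)
  X <- array(runif(16 * 16 * 4 * 4), c(16, 16, 4, 4))
  p <- nn_predict(m, X)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-10)
  expect_true(all(p >= 0))
  mv <- build_model(spec_vgg16_3d(c(16, 16, 4, 1), 3L,
                                  dense_units = c(32L, 32L)), seed = 5)
  p3 <- nn_predict(mv, array(runif(16 * 16 * 4 * 2), c(16, 16, 4, 1, 2)))
  expect_equal(rowSums(p3), rep(1, 2), tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  # 2D conv stack
  expect_lt(grad_check_spec(list(
    layer_spec("conv2d", filters = 4L, kernel = 3L, stride = 1L,
               activation = "relu", init = "he_uniform"),
    layer_spec("conv2d", filters = 6L, kernel = 3L, stride = 2L,
               activation = "relu"),
    layer_spec("flatten")), c(10, 10, 3), class_count = 3L,
    weights = c(1, 1.7, 0.6)), 1e-5)
  # 3D conv + pool + dense + dropout (dropout inert in eval mode)
  expect_lt(grad_check_spec(list(
    layer_spec("conv3d", filters = 3L, kernel = 3L, stride = 1L,
               activation = "relu", init = "he_uniform"),
    layer_spec("maxpool3d"),
    layer_spec("flatten"),
    layer_spec("dense", units = 8L, activation = "relu"),
    layer_spec("dropout", rate = 0.5)), c(6, 6, 4, 2)), 1e-5)
  # stride-2 3D conv (asymmetric same padding path)
  expect_lt(grad_check_spec(list(
    layer_spec("conv3d", filters = 4L, kernel = 2L, stride = 2L,
               activation = "relu"),
    layer_spec("flatten")), c(5, 7, 3, 2)), 1e-5)
})
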