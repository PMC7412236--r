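test_that("the FCN carries exactly the prescribed convolutional weights", {
  m <- build_network(network_spec("fcn", 16, 3))
  # 5*5*1*128 + 5*5*128*256 + 5*5*256*128
  expect_equal(conv_weight_count(m), 1641600L)
  nm <- names(m$params)
  expect_setequal(grep("^conv", nm, value = TRUE),
                  c("conv1.W", "conv1.b", "conv2.W", "conv2.b",
                    "conv3.W", "conv3.b"))
  expect_equal(dim(m$params[["conv2.W"]]), c(5 * 5 * 128, 256))
  # no fully-connected hidden layers: the only dense tensor is the softmax head
  expect_setequal(grep("^(fc|head)", nm, value = TRUE), c("head.W", "head.b"))
  expect_equal(dim(m$params[["head.W"]]), c(128, 3))
})

test_that("the residual net is three FCN-like blocks with shortcut projections", {
  m <- build_network(network_spec("resnet", 16, 2))
  nm <- names(m$params)
  for (b in 1:3)
    for (c in 1:3)
      expect_true(sprintf("block%d.conv%d.W", b, c) %in% nm)
  # only block 1 changes channel count, so only it needs a projection
  expect_true("block1.convs.W" %in% nm)
  expect_false(any(grepl("block[23]\\.convs", nm)))
  expect_equal(dim(m$params[["block2.conv1.W"]]), c(5 * 5 * 128, 128))
})

test_that("softmax outputs are probability vectors at any input size", {
  for (size in c(16L, 64L, 128L)) {
    m <- build_network(network_spec("fcn", size, 4), seed = 2)
    p <- predict_network(m, array(rnorm(size * size * 3), c(size, size, 3)))
    expect_equal(dim(p), c(3L, 4L))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("the cnn baseline halves the feature map twice and needs side >= 4", {
  m <- build_network(network_spec("cnn", 64, 2))
  # flatten feeds 32 channels of a (64/4)^2 map into the first 125-unit layer
  expect_equal(dim(m$params[["fc1.W"]]), c(16 * 16 * 32, 125))
  expect_equal(dim(m$params[["fc2.W"]]), c(125, 125))
  expect_error(network_spec("cnn", 3, 2), ">= 4")
})

test_that("a separable toy problem trains to zero error", {
  toy <- toy_image_set(10, side = 8, seed = 1)
  model <- train_network(network_spec("cnn", 8, 2), toy$images, toy$labels,
                         fast_cfg(epochs = 50, seed = 3))
  expect_equal(error_rate(classify_images(model, toy$images), toy$labels), 0)
  expect_equal(nrow(model$history), 50L)
  expect_true(all(is.finite(model$history$loss)))
})

test_that("training is reproducible from its seed", {
  toy <- toy_image_set(6, side = 8, seed = 2)
  spec <- network_spec("cnn", 8, 2)
  m1 <- train_network(spec, toy$images, toy$labels, fast_cfg(8, seed = 7))
  m2 <- train_network(spec, toy$images, toy$labels, fast_cfg(8, seed = 7))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  m3 <- train_network(spec, toy$images, toy$labels, fast_cfg(8, seed = 8))
  expect_false(identical(m3$history$loss, m1$history$loss))
})

test_that("label and input validation catch the usual mistakes", {
  toy <- toy_image_set(4, side = 8, seed = 3)
  spec <- network_spec("cnn", 8, 3)
  expect_error(train_network(spec, toy$images, rep(1L, 8), fast_cfg(2)),
               "zero samples")
  expect_error(train_network(spec, toy$images, toy$labels[-1], fast_cfg(2)),
               "labels")
  expect_error(train_network(network_spec("cnn", 8, 2),
                             array(0, c(8, 7, 4)), rep(1:2, 2), fast_cfg(2)),
               "square")
})

test_that("repeated evaluation averages per-run errors across seeds", {
  toy_tr <- toy_image_set(8, side = 8, seed = 4)
  toy_te <- toy_image_set(5, side = 8, seed = 5)
  spec <- network_spec("cnn", 8, 2)
  ev <- evaluate_repeated(spec, toy_tr$images, toy_tr$labels,
                          toy_te$images, toy_te$labels,
                          fast_cfg(30, seed = 11, n_repeats = 3))
  expect_length(ev$errors, 3L)
  expect_equal(ev$mean_error, mean(ev$errors))
  expect_lte(ev$mean_error, 0.1)  # separable problem

  one <- evaluate_repeated(spec, toy_tr$images, toy_tr$labels,
                           toy_te$images, toy_te$labels,
                           fast_cfg(30, seed = 11, n_repeats = 1))
  single <- train_network(spec, toy_tr$images, toy_tr$labels,
                          fast_cfg(30, seed = 11))
  expect_equal(one$errors,
               error_rate(classify_images(single, toy_te$images),
                          toy_te$labels))
})

test_that("training history exports as CSV", {
  toy <- toy_image_set(4, side = 8, seed = 6)
  model <- train_network(network_spec("cnn", 8, 2), toy$images, toy$labels,
                         fast_cfg(4))
  path <- tempfile(fileext = ".csv")
  write_history(model, path)
  h <- read.csv(path)
  expect_equal(names(h), c("epoch", "loss", "accuracy"))
  expect_equal(nrow(h), 4L)
})
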