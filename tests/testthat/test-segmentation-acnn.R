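test_that("atrous convolution matches the triple-loop direct summation", {
  set.seed(7)
  for (case in 1:50) {
    r <- sample(c(1, 2, 4, 8), 1)
    H <- sample(9:16, 1); W <- sample(9:16, 1)
    C <- sample(1:3, 1); Co <- sample(1:2, 1)
    fm <- array(rnorm(H * W * C), dim = c(H, W, C))
    K <- array(rnorm(9 * C * Co), dim = c(3, 3, C, Co))
    got <- atrous_conv2d(fm, atrous_conv_spec(3, 3, C, Co, r), K)
    ref <- brute_atrous(fm, K, r)
    expect_lt(max(abs(got - ref)) / max(1, max(abs(ref))), 1e-6)
  }
})

test_that("rate-1 atrous convolution is the standard convolution", {
  set.seed(8)
  fm <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 2))
  K <- array(rnorm(9 * 2), dim = c(3, 3, 2, 1))
  expect_equal(atrous_conv2d(fm, atrous_conv_spec(3, 3, 2, 1, 1), K),
               brute_atrous(fm, K, 1))
})

test_that("a unit impulse spreads to the dilated tap offsets", {
  fm <- array(0, dim = c(11, 11, 1)); fm[6, 6, 1] <- 1
  K <- array(1, dim = c(3, 3, 1, 1))
  out <- atrous_conv2d(fm, atrous_conv_spec(3, 3, 1, 1, 2), K)[, , 1]
  nz <- which(out != 0, arr.ind = TRUE)
  expect_setequal(paste(nz[, 1], nz[, 2]),
                  paste(rep(c(4, 6, 8), each = 3), rep(c(4, 6, 8), 3)))
})

test_that("an interior pixel of an all-ones input sums the 9 kernel taps", {
  fm <- array(1, dim = c(9, 9, 1))
  K <- array(1, dim = c(3, 3, 1, 1))
  out <- atrous_conv2d(fm, atrous_conv_spec(3, 3, 1, 1, 2), K)[, , 1]
  expect_equal(out[5, 5], 9)
})

test_that("rate-r atrous convolution equals convolution with a zero-inflated kernel", {
  set.seed(9)
  fm <- array(rnorm(15 * 15), dim = c(15, 15, 1))
  K <- array(rnorm(9), dim = c(3, 3, 1, 1))
  r <- 2
  K_inf <- array(0, dim = c(5, 5, 1, 1))
  K_inf[seq(1, 5, by = r), seq(1, 5, by = r), 1, 1] <- K[, , 1, 1]
  a <- atrous_conv2d(fm, atrous_conv_spec(3, 3, 1, 1, r), K)
  b <- atrous_conv2d(fm, atrous_conv_spec(5, 5, 1, 1, 1), K_inf)
  expect_equal(a, b)
})

test_that("channel mismatches and invalid specs are rejected", {
  fm <- array(0, dim = c(8, 8, 2))
  expect_error(atrous_conv2d(fm, atrous_conv_spec(3, 3, 3, 1, 1),
                             array(0, dim = c(3, 3, 3, 1))), "channel mismatch")
  expect_error(atrous_conv_spec(dilation_rate = 0), ">= 1")
  expect_error(atrous_conv_spec(kernel_height = 4), "odd")
})

test_that("the built network has 16 feature layers in 5 blocks and a wide receptive field", {
  net <- build_acnn(acnn_spec())
  convs <- Filter(function(l) l$kind == "conv", net$layers)
  expect_equal(length(convs) - 1, 16)  # 16 feature extractors + 1x1 head
  rates <- vapply(convs, function(l) l$dilation, numeric(1))
  expect_equal(sort(unique(rates[-length(rates)])), c(1, 2, 4, 8, 16))
  # dilation strictly enlarges the receptive field over an all-rate-1 stack
  plain <- acnn_spec(dilation_schedule = c(1, 1, 1, 1, 1))
  expect_gt(max(receptive_field(net)), max(receptive_field(build_acnn(plain))))
  expect_error(acnn_spec(layers_per_block = c(4, 4, 4, 4)), "per block")
  expect_error(acnn_spec(layers_per_block = c(3, 3, 3, 3, 3)), "feature layers")
  expect_error(acnn_spec(dilation_schedule = c(4, 2, 1, 8, 16)), "nondecreasing")
})

test_that("training validates masks, uses inverse-frequency weights, and lr 0 freezes weights", {
  sp <- acnn_spec(input_shape = c(16, 16, 3), layers_per_block = c(1, 1, 1, 1, 12),
                  channels_per_block = c(2, 2, 2, 2, 2))
  m <- acnn_model(sp, seed = 1)
  imgs <- lapply(1:2, function(i) array(runif(16 * 16 * 3) * 255, dim = c(16, 16, 3)))
  bad <- list(matrix(2, 16, 16), matrix(0, 16, 16))
  expect_error(train_acnn(m, imgs, bad, acnn_train_config(epochs = 1)), "\\{0, 1\\}")

  masks <- lapply(1:2, function(i) {
    mm <- matrix(0, 16, 16)
    mm[sample(256, 26)] <- 1  # ~10% lesion pixels
    mm
  })
  tr <- train_acnn(m, imgs, masks, acnn_train_config(epochs = 1, batch_size = 2), seed = 2)
  # 90/10 background/lesion: lesion weight = 9x background weight
  expect_equal(tr$class_weights[2] / tr$class_weights[1],
               sum(masks[[1]] == 0, masks[[2]] == 0) / sum(masks[[1]], masks[[2]]))
  frozen <- train_acnn(m, imgs, masks,
                       acnn_train_config(epochs = 2, learning_rate = 0, batch_size = 2),
                       seed = 2)
  expect_identical(frozen$params, m$params)
})

test_that("segmentation masks are binary and deterministic given the weights", {
  am <- trained_tiny_acnn()
  te <- generate_dataset(1, 1, 0, seed = 55, image_size = c(48, 64))
  m1 <- segment(am, te$images[[1]])
  expect_true(all(m1 %in% c(0, 1)))
  expect_identical(dim(m1), dim(te$images[[1]])[1:2])
  expect_identical(m1, segment(am, te$images[[1]]))
})

test_that("segmentation training reduces the weighted cross-entropy", {
  am <- trained_tiny_acnn()
  expect_lt(am$history[length(am$history)], am$history[1])
})

test_that("ROI cropping obeys box arithmetic, equivariance, and the empty-mask fallback", {
  img <- generate_lesion_image(random_lesion_spec("BEN", 64, 64, seed = 2))$image
  full <- matrix(1, 64, 64)
  expect_identical(crop_roi(img, full), img)

  m <- matrix(0, 64, 64); m[21:30, 31:40] <- 1
  cr <- crop_roi(img, m, margin = 2)
  expect_identical(dim(cr), c(14L, 14L, 3L))

  # shifting the mask (and image) shifts the crop
  sh <- matrix(0, 64, 64); sh[26:35, 36:45] <- 1
  img_sh <- img[c(60:64, 1:59), c(60:64, 1:59), , drop = FALSE]
  expect_identical(crop_roi(img, m, margin = 2),
                   crop_roi(img_sh, sh, margin = 2))

  expect_warning(out <- crop_roi(img, matrix(0, 64, 64)), "empty mask")
  expect_identical(out, img)
})
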