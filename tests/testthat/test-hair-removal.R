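test_that("grayscale conversion applies the luma weights exactly", {
  one <- function(rgb) {
    im <- array(0, dim = c(1, 1, 3)); im[1, 1, ] <- rgb
    rgb_to_gray(im)[1, 1]
  }
  expect_equal(one(c(255, 255, 255)), 255)
  expect_equal(one(c(0, 0, 0)), 0)
  expect_equal(one(c(255, 0, 0)), 76)  # round(0.299 * 255)
  im <- array(100, dim = c(2, 2, 3))
  expect_error(rgb_to_gray(im, weights = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("closing is extensive, idempotent, flat on constants, and matches brute force", {
  ses <- c(lapply(c(0, 45, 90, 135), function(a) structuring_element("line", 9, a)),
           list(structuring_element("disk", 2)))
  flat <- matrix(77, 20, 20)
  for (se in ses) expect_equal(morphological_close(flat, se), flat)

  set.seed(42)
  for (rep in 1:6) {
    g <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    se <- ses[[((rep - 1) %% length(ses)) + 1]]
    cl <- morphological_close(g, se)
    expect_true(all(cl >= g))                          # extensivity
    expect_equal(morphological_close(cl, se), cl)      # idempotence
    expect_equal(cl, brute_close(g, se$footprint))     # two-pass max/min oracle
  }
})

test_that("a thin dark line is raised to the background by a crossing line element", {
  g <- matrix(200, 40, 40)
  g[, 20] <- 40  # 1-px vertical dark line
  se <- structuring_element("line", 15, 0)  # horizontal element crosses it
  cl <- morphological_close(g, se)
  expect_true(all(cl[, 20] == 200))
})

test_that("closing rejects an element larger than the image", {
  expect_error(morphological_close(matrix(0, 8, 8), structuring_element("line", 21, 0)),
               "larger than the image")
})

test_that("the closing residue is nonnegative, zero on constants, and covers the hairs", {
  cfg <- hair_removal_config()
  flat <- matrix(128, 30, 30)
  d0 <- hair_difference(morphological_close(flat, cfg$closing_elements[[1]]), flat)
  expect_true(all(d0 == 0))
  expect_error(hair_difference(matrix(0, 4, 4), matrix(0, 5, 5)), "shapes")

  g <- generate_lesion_image(random_lesion_spec("BEN", 96, 96, seed = 3))
  hh <- add_hairs(g$image, hair_overlay_spec(n_hairs = 5, thickness_px = 2, seed = 4))
  gray <- rgb_to_gray(hh$image)
  closed <- Reduce(pmax, lapply(cfg$closing_elements,
                                function(se) morphological_close(gray, se)))
  diff <- hair_difference(closed, gray)
  expect_gte(min(diff), 0)
  covered <- sum(diff > 0 & hh$mask == 1) / sum(hh$mask)
  expect_gte(covered, 0.7)
})

test_that("thresholding and dilation behave like their definitions", {
  cfg <- hair_removal_config()
  z <- binarize_and_dilate(matrix(0, 16, 16), cfg)
  expect_equal(sum(z$detection), 0)
  expect_equal(sum(z$mask), 0)

  d <- matrix(0, 16, 16); d[8, 8] <- 30  # single pixel above T = 25
  r <- binarize_and_dilate(d, cfg)
  expect_equal(sum(r$detection), 1)
  fp <- cfg$dilation_element$footprint
  ref <- matrix(0, 16, 16)
  off <- which(fp == 1, arr.ind = TRUE) - 3  # disc radius 2, centred anchor
  ref[cbind(8 + off[, 1], 8 + off[, 2])] <- 1
  expect_equal(r$mask, ref)
  expect_true(all(r$mask[r$detection == 1] == 1))  # dilation never shrinks
})

test_that("inpainting honours its identity and donor contracts", {
  g <- generate_lesion_image(random_lesion_spec("BEN", 64, 64, seed = 8))
  empty <- matrix(0, 64, 64)
  expect_identical(inpaint_hairs(g$image, empty), g$image)

  const <- array(90, dim = c(32, 32, 3))
  m <- matrix(0, 32, 32); m[10:12, 5:25] <- 1
  expect_identical(inpaint_hairs(const, m), const)

  full <- matrix(1, 16, 16)
  expect_error(inpaint_hairs(array(1, dim = c(16, 16, 3)), full), "donor")

  hh <- add_hairs(g$image, hair_overlay_spec(n_hairs = 4, thickness_px = 2, seed = 5))
  out <- inpaint_hairs(hh$image, hh$mask)
  keep <- rep(hh$mask == 0, 3)
  expect_identical(out[keep], hh$image[keep])  # bit-exact off the mask
  # repainted pixels approximate the hair-free original
  err <- mean(abs(out - g$image)[rep(hh$mask == 1, 3)])
  expect_lt(err, 10)
})

test_that("the full pipeline stays quiet on hair-free images and recovers hairy ones", {
  smooth <- generate_lesion_image(synth_lesion_spec(seed = 5))
  r0 <- remove_hairlines(smooth$image)
  expect_lt(mean(r0$detection_mask), 0.01)

  g <- generate_lesion_image(random_lesion_spec("BEN", 96, 96, seed = 3))
  hh <- add_hairs(g$image, hair_overlay_spec(n_hairs = 5, thickness_px = 2, seed = 4))
  r <- remove_hairlines(hh$image)
  expect_gte(dice_coefficient(r$detection_mask, hh$mask), 0.7)
  keep <- rep(r$mask == 0, 3)
  expect_identical(r$image[keep], hh$image[keep])
})
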