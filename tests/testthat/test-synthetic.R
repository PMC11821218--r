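test_that("lesion generation is deterministic and rasterizes the ellipse exactly", {
  sp <- synth_lesion_spec(seed = 7)
  g1 <- generate_lesion_image(sp)
  g2 <- generate_lesion_image(sp)
  expect_identical(g1, g2)
  expect_true(all(g1$mask %in% c(0, 1)))
  expect_identical(dim(g1$mask), dim(g1$image)[1:2])

  # irregularity 0: mask is a filled ellipse; compare to the analytic area
  area <- sum(g1$mask)
  expect_lt(abs(area - pi * prod(sp$lesion_axes)) / (pi * prod(sp$lesion_axes)), 0.02)
  # and to an independent per-pixel inside test
  H <- sp$image_height; W <- sp$image_width
  dr <- matrix(seq_len(H) - sp$lesion_center[1], H, W)
  dc <- matrix(seq_len(W) - sp$lesion_center[2], H, W, byrow = TRUE)
  ref <- ((dr / sp$lesion_axes[1])^2 + (dc / sp$lesion_axes[2])^2 <= 1) * 1
  expect_identical(g1$mask, ref)
})

test_that("an out-of-frame lesion spec is rejected", {
  expect_error(synth_lesion_spec(lesion_center = c(5, 64), seed = 1),
               "inside")
})

test_that("MEL lesions are darker than BEN lesions", {
  for (s in 1:5) {
    mel <- generate_lesion_image(random_lesion_spec("MEL", seed = s))
    ben <- generate_lesion_image(random_lesion_spec("BEN", seed = s + 50))
    mean_in <- function(g) mean(g$image[rep(g$mask == 1, 3)])
    expect_gt(mean_in(ben), mean_in(mel))
  }
})

test_that("hair overlay changes exactly the mask support and is seed-sensitive", {
  g <- generate_lesion_image(random_lesion_spec("BEN", seed = 3))
  h0 <- add_hairs(g$image, hair_overlay_spec(n_hairs = 0, seed = 1))
  expect_identical(h0$image, g$image)
  expect_equal(sum(h0$mask), 0)

  sp <- hair_overlay_spec(n_hairs = 5, thickness_px = 2, seed = 4)
  hh <- add_hairs(g$image, sp)
  changed <- (apply(hh$image != g$image, c(1, 2), any)) * 1
  expect_identical(changed, hh$mask)
  expect_gte(sum(hh$mask), 5)  # at least one pixel per hair
  # drawn pixels are strictly darker in every channel
  idx <- which(hh$mask == 1)
  for (ch in 1:3) {
    expect_true(all(hh$image[, , ch][idx] < g$image[, , ch][idx]))
  }
  h2 <- add_hairs(g$image, hair_overlay_spec(n_hairs = 5, thickness_px = 2, seed = 99))
  expect_false(identical(hh$mask, h2$mask))
  expect_identical(add_hairs(g$image, sp)$image, hh$image)
})

test_that("contrast degradation follows the gamma/gain closed form", {
  g <- generate_lesion_image(random_lesion_spec("BEN", seed = 5))
  expect_identical(degrade_contrast(g$image, 1, 1), g$image)
  mid <- array(128, dim = c(4, 4, 3))
  expect_true(all(degrade_contrast(mid, 2, 1) == round_half_up(255 * (128 / 255)^2)))
  expect_equal(unique(as.vector(degrade_contrast(mid, 2, 1))), 64)
  out <- degrade_contrast(g$image, 0.3, 3)
  expect_true(min(out) >= 0 && max(out) <= 255)
  expect_error(degrade_contrast(g$image, 0, 1), "positive")
  expect_error(degrade_contrast(g$image, 1, -2), "positive")
})

test_that("near-duplicates sit on the expected side of the 0.99 correlation bar", {
  g <- generate_lesion_image(random_lesion_spec("MEL", seed = 11))
  expect_identical(make_near_duplicate(g$image, 0), g$image)
  d2 <- make_near_duplicate(g$image, 2, seed = 3)
  expect_gt(pearson_correlation(g$image, d2), 0.99)
  d80 <- make_near_duplicate(g$image, 80, seed = 3)
  expect_lt(pearson_correlation(g$image, d80), 0.99)
})

test_that("dataset generation yields the requested counts and duplicate flags", {
  ds <- generate_dataset(10, 10, 0.2, seed = 13, image_size = c(48, 48))
  expect_equal(nrow(ds$index), 24)
  expect_equal(sum(!is.na(ds$index$is_duplicate_of)), 4)
  expect_equal(sum(ds$index$label == "MEL" & is.na(ds$index$is_duplicate_of)), 10)
  expect_setequal(names(ds$images), ds$index$path)
  # flagged duplicates really correlate with their source
  for (r in which(!is.na(ds$index$is_duplicate_of))) {
    expect_gt(pearson_correlation(ds$images[[ds$index$path[r]]],
                                  ds$images[[ds$index$is_duplicate_of[r]]]), 0.99)
  }
})

test_that("without duplicates no distinct pair crosses the 0.99 bar", {
  ds <- generate_dataset(5, 5, 0, seed = 17, image_size = c(48, 48))
  n <- nrow(ds$index)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      expect_lt(pearson_correlation(ds$images[[i]], ds$images[[j]]), 0.99)
    }
  }
})

test_that("classes are separable by a trivial intensity threshold", {
  ds <- generate_dataset(25, 25, 0, seed = 19, image_size = c(64, 64))
  means <- vapply(ds$images, mean, numeric(1))
  labs <- ds$index$label
  # threshold at the midpoint of the class means
  thr <- mean(c(mean(means[labs == "MEL"]), mean(means[labs == "BEN"])))
  acc <- mean(ifelse(means < thr, "MEL", "BEN") == labs)
  expect_gt(acc, 0.8)
})
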