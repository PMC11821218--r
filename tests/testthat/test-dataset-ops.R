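test_that("image correlation matches the textbook formula and handles edge cases", {
  g <- generate_lesion_image(random_lesion_spec("BEN", 64, 64, seed = 1))$image
  expect_equal(pearson_correlation(g, g), 1.0)
  gm <- rgb_to_gray(g)
  expect_equal(pearson_correlation(gm, 255 - gm), -1.0)
  set.seed(2)
  a <- matrix(runif(400), 20, 20); b <- matrix(runif(400), 20, 20)
  ref <- mean((a - mean(a)) * (b - mean(b))) /
    sqrt(mean((a - mean(a))^2) * mean((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), ref, tolerance = 1e-10)
  expect_warning(z <- pearson_correlation(matrix(5, 8, 8), a), "constant")
  expect_equal(z, 0)
})

test_that("deduplication removes flagged duplicates, keeps firsts, and is idempotent", {
  ds <- generate_dataset(10, 10, 0.2, seed = 13, image_size = c(48, 48))
  out <- deduplicate(ds$index, ds$images)
  expect_equal(nrow(out), 20)
  expect_true(all(is.na(out$is_duplicate_of)))          # originals kept
  expect_identical(deduplicate(out, ds$images), out)    # idempotence

  clean <- generate_dataset(4, 4, 0, seed = 14, image_size = c(48, 48))
  expect_identical(deduplicate(clean$index, clean$images), clean$index)
})

test_that("three mutual duplicates collapse to one representative", {
  g <- generate_lesion_image(random_lesion_spec("MEL", 64, 64, seed = 5))$image
  imgs <- list(a.png = g, b.png = make_near_duplicate(g, 1, seed = 1),
               c.png = make_near_duplicate(g, 1, seed = 2))
  idx <- data.frame(path = names(imgs), label = "MEL", patient_id = "P1",
                    is_duplicate_of = NA, stringsAsFactors = FALSE)
  out <- deduplicate(idx, imgs)
  expect_equal(out$path, "a.png")
})

test_that("largest-remainder 70/10/20 split reproduces the reference class totals", {
  mk <- function(n, label) data.frame(path = sprintf("%s_%d.png", label, 1:n),
                                      label = label, stringsAsFactors = FALSE)
  idx <- rbind(mk(5789, "MEL"), mk(7093, "BEN"))
  sp <- stratified_split(idx, seed = 3)
  tab <- table(sp$label, sp$split)
  expect_equal(as.integer(tab["MEL", c("train", "val", "test")]), c(4052L, 579L, 1158L))
  expect_equal(as.integer(tab["BEN", c("train", "val", "test")]), c(4965L, 709L, 1419L))
  expect_equal(sum(tab), 12882)

  small <- stratified_split(mk(10, "MEL"), seed = 1)
  expect_equal(as.integer(table(small$split)[c("train", "val", "test")]), c(7L, 1L, 2L))
  expect_error(stratified_split(mk(2, "BEN")), "fewer than 3")
  expect_error(stratified_split(mk(10, "MEL"), fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("oversampling balances the training split and protects val/test", {
  mk <- function(n, label) data.frame(path = sprintf("%s_%d.png", label, 1:n),
                                      label = label, split = "train",
                                      stringsAsFactors = FALSE)
  tr <- rbind(mk(4052, "MEL"), mk(4965, "BEN"))
  out <- random_oversample(tr, seed = 2)
  expect_equal(as.integer(table(out$label)["MEL"]), 4965L)
  expect_equal(nrow(out), 9930)

  bal <- rbind(mk(5, "MEL"), mk(5, "BEN"))
  expect_identical(random_oversample(bal, seed = 1), bal)

  toy <- rbind(mk(3, "MEL"), mk(5, "BEN"))
  out2 <- random_oversample(toy, seed = 1)
  expect_equal(as.integer(table(out2$label)), c(5L, 5L))

  bad <- tr; bad$split[1] <- "test"
  expect_error(random_oversample(bad), "training split only")
})

test_that("augmentation is identity-exact, shifts impulses, and is seeded", {
  img <- generate_lesion_image(random_lesion_spec("BEN", 64, 64, seed = 4))$image
  ident <- augmentation_config(rotation_range = c(0, 0), scale_x = 1,
                               translate_y = c(0, 0), seed = 1)
  expect_identical(augment(img, ident), img)

  imp <- array(0, dim = c(32, 32, 3)); imp[10, 16, ] <- 255
  shift <- augmentation_config(rotation_range = c(0, 0), scale_x = 1,
                               translate_y = c(5, 5), seed = 1)
  out <- augment(imp, shift)
  expect_equal(out[15, 16, 1], 255)
  expect_equal(sum(out), 3 * 255)

  cfg <- augmentation_config(seed = 7)
  a1 <- augment(img, cfg); a2 <- augment(img, cfg)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(img))
  expect_false(identical(a1, augment(img, augmentation_config(seed = 8))))
})

test_that("the index CSV round-trips", {
  ds <- generate_dataset(3, 3, 0, seed = 1, image_size = c(32, 32))
  idx <- stratified_split(ds$index, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_index_csv(idx, f)
  back <- read_index_csv(f)
  expect_equal(back$path, idx$path)
  expect_equal(back$label, idx$label)
  expect_equal(back$split, idx$split)
  unlink(f)
})
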