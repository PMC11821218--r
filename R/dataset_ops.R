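#' Pearson correlation between two images
#'
#' Standard Pearson coefficient over flattened grayscale intensities; images
#' of different sizes are first resized to a common 256 x 256 raster. Used to
#' detect near-duplicate acquisitions (threshold 0.99).
#'
#' @param image_a,image_b RGB arrays or grayscale matrices.
#' @param common_size resampling size applied when the inputs differ in size.
#' @return correlation in \[-1, 1\]; 0 (with a warning) when either image is
#'   constant.
#' @export
pearson_correlation <- function(image_a, image_b, common_size = c(256, 256)) {
  to_gray <- function(x) if (is.matrix(x)) x else rgb_to_gray(x)
  a <- to_gray(image_a); b <- to_gray(image_b)
  if (!identical(dim(a), dim(b))) {
    a <- resize_image(a, common_size[1], common_size[2])
    b <- resize_image(b, common_size[1], common_size[2])
  }
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant image in correlation; defined as 0")
    return(0)
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Remove near-duplicate images from a dataset index
#'
#' Images of the same class are compared pairwise; pairs with Pearson
#' correlation above `threshold` are grouped by transitive closure, and one
#' representative per group — the first in index (path) order — is kept.
#' Idempotent: a deduplicated index passes through unchanged.
#'
#' @param index data.frame with at least `path` and `label` columns.
#' @param images named list of images keyed by `path`.
#' @param threshold correlation threshold (default 0.99).
#' @return the filtered index (rows of retained images, original order).
#' @export
deduplicate <- function(index, images, threshold = 0.99) {
  n <- nrow(index)
  if (n < 2) return(index)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  gray <- lapply(index$path, function(p) {
    im <- images[[p]]
    if (is.matrix(im)) im else rgb_to_gray(im)
  })
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (index$label[i] != index$label[j]) next
      if (find(i) == find(j)) next
      if (pearson_correlation(gray[[i]], gray[[j]]) > threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- !duplicated(root)  # first row of each duplicate group survives
  index[keep, , drop = FALSE]
}

largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Per class, the 70/10/20 shares are apportioned by the largest-remainder
#' rule (so split counts sum exactly to the class total) and the assignment
#' is randomized by `seed`. Class totals of 5,789 and 7,093 apportion to
#' (4052, 579, 1158) and (4965, 709, 1419).
#'
#' @param index data.frame with a `label` column.
#' @param fractions `(train, val, test)` shares summing to 1.
#' @param seed integer seed.
#' @return the index with a `split` column in `{train, val, test}`.
#' @export
stratified_split <- function(index, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1", call. = FALSE)
  index$split <- NA_character_
  with_seed(seed, {
    for (cl in unique(index$label)) {
      rows <- which(index$label == cl)
      if (length(rows) < 3) {
        stop(sprintf("class %s has fewer than 3 images; cannot split", cl),
             call. = FALSE)
      }
      counts <- largest_remainder(length(rows), fractions)
      assign_ <- rep(c("train", "val", "test"), counts)
      index$split[rows] <- sample(assign_)
    }
  })
  index
}

#' Random oversampling of the minority class
#'
#' Training-split records of the minority class are duplicated (sampled with
#' replacement, seeded) until both class counts equal the majority count.
#' Validation/test records must not be passed in: their original distribution
#' is preserved by contract.
#'
#' @param train_index training-split index (every row with `split == "train"`
#'   or no split column).
#' @param seed integer seed.
#' @return the augmented index; already balanced input is returned unchanged.
#' @export
random_oversample <- function(train_index, seed = 1L) {
  if ("split" %in% names(train_index) &&
      any(train_index$split != "train")) {
    stop("random oversampling applies to the training split only", call. = FALSE)
  }
  tab <- table(train_index$label)
  if (length(tab) < 2 || max(tab) == min(tab)) return(train_index)
  minority <- names(tab)[which.min(tab)]
  deficit <- max(tab) - min(tab)
  rows <- which(train_index$label == minority)
  extra <- with_seed(seed, sample(rows, deficit, replace = TRUE))
  out <- rbind(train_index, train_index[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Augmentation configuration
#'
#' Seeded geometric training-set augmentation: rotation uniformly drawn from
#' `rotation_range` degrees, fixed horizontal scale `scale_x`, vertical
#' translation uniformly drawn from `translate_y` pixels.
#'
#' @param rotation_range `(min, max)` rotation in degrees (default -30..30).
#' @param scale_x horizontal scale factor (default 0.8).
#' @param translate_y `(min, max)` vertical shift in pixels (default -5..5).
#' @param seed integer seed.
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_range = c(-30, 30), scale_x = 0.8,
                                translate_y = c(-5, 5), seed = 1L) {
  structure(list(rotation_range = rotation_range, scale_x = scale_x,
                 translate_y = translate_y, seed = as.integer(seed)),
            class = "augmentation_config")
}

# reflect an index vector into 1..n
reflect_index <- function(i, n) {
  period <- 2 * n
  i <- ((i - 1) %% period + period) %% period + 1
  ifelse(i > n, period - i + 1, i)
}

# inverse-mapped affine warp (rotation about the centre, x-scale, y-shift)
# with bilinear sampling and reflect padding; exact for integer shifts
warp_affine <- function(image, angle_deg, scale_x, ty) {
  H <- dim(image)[1]; W <- dim(image)[2]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H) - cy, H, W) - ty
  cc <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  # inverse rotation then inverse scale
  sr <- r * cos(th) - cc * sin(th)
  sc <- (r * sin(th) + cc * cos(th)) / scale_x
  sr <- sr + cy; sc <- sc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(as.vector(reflect_index(r0, H)), as.vector(reflect_index(c0, W)))
  i10 <- cbind(as.vector(reflect_index(r0 + 1, H)), as.vector(reflect_index(c0, W)))
  i01 <- cbind(as.vector(reflect_index(r0, H)), as.vector(reflect_index(c0 + 1, W)))
  i11 <- cbind(as.vector(reflect_index(r0 + 1, H)), as.vector(reflect_index(c0 + 1, W)))
  out <- image
  for (ch in 1:3) {
    p <- image[, , ch]
    v <- p[i00] * (1 - fr) * (1 - fc) + p[i10] * fr * (1 - fc) +
      p[i01] * (1 - fr) * fc + p[i11] * fr * fc
    out[, , ch] <- matrix(v, H, W)
  }
  as_uint8(out)
}

#' Apply seeded geometric augmentation to a training image
#'
#' Rotation, horizontal scaling and vertical translation with reflect
#' padding; the output shape equals the input shape. The identity
#' configuration (0 degrees, scale 1, 0 px) returns the input unchanged, and
#' a fixed seed always yields the same output.
#'
#' @param image H x W x 3 array, 0-255.
#' @param cfg an [augmentation_config()].
#' @return augmented image, same shape.
#' @export
augment <- function(image, cfg = augmentation_config()) {
  assert_rgb_image(image)
  stopifnot(inherits(cfg, "augmentation_config"))
  d <- with_seed(cfg$seed, list(
    ang = runif(1, cfg$rotation_range[1], cfg$rotation_range[2]),
    ty = runif(1, cfg$translate_y[1], cfg$translate_y[2])))
  if (d$ang == 0 && cfg$scale_x == 1 && d$ty == 0) return(image)
  warp_affine(image, d$ang, cfg$scale_x, d$ty)
}

#' Read / write a dataset index CSV
#'
#' Columns: `path,label,patient_id` plus `is_duplicate_of` and/or `split`
#' when present.
#'
#' @param index a dataset index data.frame.
#' @param path CSV file path.
#' @return the index data.frame (reader); invisibly `path` (writer).
#' @export
write_index_csv <- function(index, path) {
  write.csv(index, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_index_csv
#' @export
read_index_csv <- function(path) {
  idx <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  idx$path <- as.character(idx$path)
  idx
}
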