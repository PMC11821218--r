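#' @useDynLib dermocad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif predict sd
#' @importFrom utils read.csv write.csv
NULL

# images are plain numeric arrays H x W x 3 (or H x W matrices when
# grayscale) holding integral intensities on the 8-bit 0..255 scale; masks
# are H x W matrices in {0, 1}.

#' Round half away from zero
#'
#' Plain arithmetic rounding (0.5 always rounds up), used everywhere an
#' 8-bit intensity or a reported percentage is produced, so that worked
#' examples are exact.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Clamp to the 8-bit range and round
#' @param x numeric array of intensities.
#' @return the same array with integral values in \[0, 255\].
#' @export
as_uint8 <- function(x) clip(round_half_up(x), 0, 255)

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

assert_rgb_image <- function(x, name = "image") {
  if (!is_rgb_image(x)) {
    stop(sprintf("`%s` must be an H x W x 3 numeric array", name), call. = FALSE)
  }
  if (min(x) < 0 || max(x) > 255) {
    stop(sprintf("`%s` must hold 8-bit intensities in [0, 255]", name), call. = FALSE)
  }
  invisible(x)
}

assert_gray_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric H x W matrix", name), call. = FALSE)
  }
  invisible(x)
}

assert_mask <- function(mask, image = NULL, name = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop(sprintf("`%s` must be a binary H x W matrix", name), call. = FALSE)
  }
  if (!is.null(image) && !identical(dim(mask), dim(image)[1:2])) {
    stop(sprintf("`%s` dimensions do not match the image", name), call. = FALSE)
  }
  invisible(mask)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a child seed from a base seed, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b binary matrices of identical dimensions.
#' @return `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# ---- EBImage bridges (EBImage stores x = width as the first dimension) ----

eb_from_mat <- function(m) EBImage::Image(t(m))
eb_to_mat <- function(e) t(EBImage::imageData(e))

#' Resize an image or mask
#'
#' Bilinear resampling for images, nearest neighbour for binary masks
#' (so mask values stay in \{0, 1\}).
#'
#' @param x RGB array, grayscale matrix, or binary mask matrix.
#' @param height,width target size in pixels.
#' @param mask logical; treat `x` as a binary mask.
#' @return resized array/matrix on the same intensity scale.
#' @export
resize_image <- function(x, height, width, mask = FALSE) {
  filt <- if (mask) "none" else "bilinear"
  if (is.matrix(x)) {
    out <- eb_to_mat(EBImage::resize(eb_from_mat(x), w = width, h = height,
                                     filter = filt))
    if (mask) out <- (out > 0.5) * 1
    return(out)
  }
  assert_rgb_image(x)
  e <- EBImage::Image(aperm(x, c(2, 1, 3)) / 255, colormode = "Color")
  r <- EBImage::resize(e, w = width, h = height, filter = filt)
  as_uint8(aperm(EBImage::imageData(r), c(2, 1, 3)) * 255)
}

# ---- PNG I/O ----

#' Read / write 8-bit PNG images and masks
#'
#' Images are stored as H x W x 3 arrays of 0..255 intensities; masks as
#' 0/255 single-channel PNGs mapped to 0/1 matrices.
#'
#' @param path file path.
#' @param image RGB array for `write_image_png`.
#' @param mask binary matrix for `write_mask_png`.
#' @return the image array or mask matrix (readers); invisibly `path` (writers).
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  as_uint8(a * 255)
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  (a > 0.5) * 1
}

#' @rdname read_image_png
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask, path)
  invisible(path)
}
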