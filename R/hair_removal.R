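#' Structuring elements for grayscale morphology
#'
#' Line elements (given length and orientation) or discs (given radius),
#' realized as odd-sized binary footprints so the anchor is centred.
#'
#' @param shape `"line"` or `"disk"`.
#' @param length_or_radius line length, or disc radius, in pixels.
#' @param orientation line orientation in degrees (ignored for disks).
#' @return an object of class `structuring_element` wrapping the binary
#'   footprint matrix.
#' @export
structuring_element <- function(shape = c("line", "disk"), length_or_radius,
                                orientation = 0) {
  shape <- match.arg(shape)
  if (shape == "line") {
    len <- as.integer(length_or_radius)
    if (len %% 2 == 0) len <- len + 1L  # centred anchor needs an odd footprint
    # rasterized directly (handles every orientation uniformly)
    h <- (len - 1L) / 2L
    t <- seq(-h, h, by = 0.5)
    th <- orientation * pi / 180
    dr <- round(-t * sin(th)); dc <- round(t * cos(th))
    ext <- max(abs(c(dr, dc)))
    fp <- matrix(0L, 2 * ext + 1, 2 * ext + 1)
    fp[cbind(dr + ext + 1, dc + ext + 1)] <- 1L
    # trim to the bounding box (symmetric, so the anchor stays centred)
    rr <- range(which(rowSums(fp) > 0)); cc <- range(which(colSums(fp) > 0))
    fp <- fp[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  } else {
    r <- as.integer(length_or_radius)
    fp <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  }
  structure(list(shape = shape, length_or_radius = length_or_radius,
                 orientation = orientation, footprint = fp),
            class = "structuring_element")
}

#' Hair-removal configuration
#'
#' Houses the detection threshold and the structuring elements of the
#' morphological hairline pipeline. The default closing bank uses line
#' elements of length 15 at orientations 0/45/90/135 degrees (thin dark hairs
#' have unknown orientation; the per-pixel maximum over the four closings
#' fills a hair whenever at least one element crosses it), a detection
#' threshold of 25 intensity units on the 0-255 scale, and a disc of radius 2
#' for the mask-repair dilation.
#'
#' @param closing_elements list of line [structuring_element()]s.
#' @param threshold_T detection threshold, intensity units in (0, 255).
#' @param dilation_element structuring element for the mask dilation.
#' @param grayscale_weights RGB luma weights, must sum to 1.
#' @return an object of class `hair_removal_config`.
#' @export
hair_removal_config <- function(
    closing_elements = lapply(c(0, 45, 90, 135), function(a)
      structuring_element("line", 15, a)),
    threshold_T = 25,
    dilation_element = structuring_element("disk", 2),
    grayscale_weights = c(0.299, 0.587, 0.114)) {
  if (threshold_T <= 0 || threshold_T >= 255) {
    stop("`threshold_T` must lie strictly between 0 and 255", call. = FALSE)
  }
  structure(list(closing_elements = closing_elements, threshold_T = threshold_T,
                 dilation_element = dilation_element,
                 grayscale_weights = grayscale_weights),
            class = "hair_removal_config")
}

#' Convert an RGB image to weighted grayscale
#'
#' @param image H x W x 3 array, 0-255.
#' @param weights RGB weights summing to 1 (default standard luma).
#' @return H x W matrix of integral intensities, 0-255 (rounded half-up).
#' @export
rgb_to_gray <- function(image, weights = c(0.299, 0.587, 0.114)) {
  assert_rgb_image(image)
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("grayscale `weights` must sum to 1", call. = FALSE)
  }
  g <- image[, , 1] * weights[1] + image[, , 2] * weights[2] +
    image[, , 3] * weights[3]
  as_uint8(matrix(g, dim(image)[1], dim(image)[2]))
}

#' Grayscale morphological closing
#'
#' Dilation followed by erosion with the same structuring element. Closing is
#' extensive (result >= input everywhere) and idempotent; dark structures
#' thinner than the element are raised to their surroundings, which is what
#' exposes hairs in the subsequent subtraction.
#'
#' @param gray H x W grayscale matrix.
#' @param se a [structuring_element()].
#' @return closed grayscale matrix, same shape.
#' @export
morphological_close <- function(gray, se) {
  assert_gray_image(gray)
  stopifnot(inherits(se, "structuring_element"))
  fp <- se$footprint
  if (nrow(fp) > nrow(gray) || ncol(fp) > ncol(gray)) {
    stop("structuring element is larger than the image", call. = FALSE)
  }
  # EBImage works on the [0, 1] scale with x (width) as the first kernel
  # dimension, hence the rescale and the footprint transpose; rounding clears
  # float dust so extensivity/idempotence hold exactly on integral inputs
  round_half_up(255 * eb_to_mat(EBImage::closing(eb_from_mat(gray / 255), t(fp))), 6)
}

# per-pixel maximum over the bank of line closings
closing_bank <- function(gray, elements) {
  out <- morphological_close(gray, elements[[1]])
  for (se in elements[-1]) out <- pmax(out, morphological_close(gray, se))
  out
}

#' Difference between a closed image and the original
#'
#' Nonnegative by extensivity of closing; large exactly on the thin dark
#' structures that the closing filled.
#'
#' @param close_img closed grayscale matrix.
#' @param gray original grayscale matrix, same shape.
#' @return difference matrix `close_img - gray`.
#' @export
hair_difference <- function(close_img, gray) {
  assert_gray_image(close_img); assert_gray_image(gray)
  if (!identical(dim(close_img), dim(gray))) {
    stop("closed image and original have different shapes", call. = FALSE)
  }
  close_img - gray
}

#' Threshold the difference image and dilate the resulting mask
#'
#' Pixels whose closing residue exceeds `threshold_T` form the detection
#' mask; a binary dilation then repairs boundaries and bridges small gaps so
#' the mask safely covers the hair for inpainting. Dilation only grows the
#' mask, never shrinks it.
#'
#' @param diff nonnegative difference matrix from [hair_difference()].
#' @param cfg a [hair_removal_config()].
#' @return list with `detection` (thresholded mask) and `mask` (dilated mask),
#'   both binary H x W matrices.
#' @export
binarize_and_dilate <- function(diff, cfg = hair_removal_config()) {
  assert_gray_image(diff, "diff")
  detection <- (diff > cfg$threshold_T) * 1
  dil <- EBImage::dilate(eb_from_mat(detection), t(cfg$dilation_element$footprint))
  list(detection = detection, mask = (eb_to_mat(dil) > 0) * 1)
}

#' Repaint masked pixels from their nearest unmasked neighbours
#'
#' Pixels outside the mask are returned bit-identically; each masked pixel
#' receives, per channel, the inverse-distance-weighted average of its
#' `k` nearest unmasked pixels. Deterministic and order-independent.
#'
#' @param image H x W x 3 array, 0-255.
#' @param mask binary H x W matrix aligned to the image.
#' @param k number of donor pixels per masked pixel.
#' @return inpainted image, same shape.
#' @export
inpaint_hairs <- function(image, mask, k = 8) {
  assert_rgb_image(image)
  assert_mask(mask, image)
  bad <- which(mask == 1)
  if (length(bad) == 0) return(image)
  good <- which(mask == 0)
  if (length(good) == 0) {
    stop("mask covers the entire image: no donor pixels to repaint from", call. = FALSE)
  }
  H <- dim(image)[1]
  br <- (bad - 1) %% H + 1; bc <- (bad - 1) %/% H + 1
  gr <- (good - 1) %% H + 1; gc <- (good - 1) %/% H + 1
  k <- min(k, length(good))
  ch1 <- image[, , 1][good]; ch2 <- image[, , 2][good]; ch3 <- image[, , 3][good]
  out <- image
  fill <- matrix(0, length(bad), 3)
  # chunked brute-force nearest-donor search keeps memory bounded
  step <- max(1L, as.integer(2e6 / length(good)))
  for (s in seq(1, length(bad), by = step)) {
    e <- min(s + step - 1, length(bad))
    d2 <- outer(br[s:e], gr, "-")^2 + outer(bc[s:e], gc, "-")^2
    for (i in seq_len(e - s + 1)) {
      nn <- order(d2[i, ])[seq_len(k)]
      w <- 1 / sqrt(d2[i, nn])
      w <- w / sum(w)
      fill[s + i - 1, ] <- c(sum(w * ch1[nn]), sum(w * ch2[nn]), sum(w * ch3[nn]))
    }
  }
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[bad] <- fill[, ch]
    out[, , ch] <- as_uint8(plane)
  }
  out
}

#' Full hairline removal pipeline
#'
#' Grayscale conversion, a bank of line closings combined by per-pixel
#' maximum, subtraction, thresholding, mask dilation, and neighbour-intensity
#' repainting. Pixels outside the (dilated) inpainting mask are returned
#' bit-identically.
#'
#' @param image H x W x 3 array, 0-255.
#' @param cfg a [hair_removal_config()].
#' @return list with `image` (cleaned), `mask` (dilated mask actually
#'   inpainted), and `detection_mask` (pre-dilation detection support, the
#'   mask scored against ground truth hair masks).
#' @export
remove_hairlines <- function(image, cfg = hair_removal_config()) {
  assert_rgb_image(image)
  gray <- rgb_to_gray(image, cfg$grayscale_weights)
  closed <- closing_bank(gray, cfg$closing_elements)
  diff <- hair_difference(closed, gray)
  m <- binarize_and_dilate(diff, cfg)
  cleaned <- inpaint_hairs(image, m$mask)
  list(image = cleaned, mask = m$mask, detection_mask = m$detection)
}
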