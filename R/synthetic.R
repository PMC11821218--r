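#' Synthetic lesion specification
#'
#' Describes one synthetic dermoscopic-like image: an elliptical lesion with a
#' sinusoidally perturbed border on a textured skin background. Melanoma-like
#' (MEL) specs are darker, multi-toned and more irregular than benign (BEN)
#' ones, so the two classes are separable by design.
#'
#' @param image_height,image_width frame size in pixels.
#' @param lesion_center `(row, col)` of the lesion centre, pixels.
#' @param lesion_axes `(a, b)` ellipse semi-axes, pixels.
#' @param lesion_rotation ellipse rotation, degrees.
#' @param lesion_color RGB triple (0-255) of the lesion body.
#' @param skin_color RGB triple of the surrounding skin.
#' @param texture_noise_sd per-pixel Gaussian texture noise, intensity units.
#' @param border_irregularity amplitude in `[0, 1]` of the radial border
#'   perturbation (0 = exact ellipse).
#' @param class_label `"MEL"` or `"BEN"`.
#' @param seed integer seed; the generated image is a pure function of
#'   (spec, seed).
#' @return an object of class `synth_lesion_spec`.
#' @export
synth_lesion_spec <- function(image_height = 128, image_width = 128,
                              lesion_center = c(image_height / 2, image_width / 2),
                              lesion_axes = c(0.25 * image_height, 0.2 * image_width),
                              lesion_rotation = 0,
                              lesion_color = c(160, 110, 95),
                              skin_color = c(196, 150, 130),
                              texture_noise_sd = 4,
                              border_irregularity = 0,
                              class_label = c("BEN", "MEL"),
                              seed = 1L) {
  class_label <- match.arg(class_label)
  spec <- structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    lesion_center = as.numeric(lesion_center), lesion_axes = as.numeric(lesion_axes),
    lesion_rotation = as.numeric(lesion_rotation),
    lesion_color = as.numeric(lesion_color), skin_color = as.numeric(skin_color),
    texture_noise_sd = as.numeric(texture_noise_sd),
    border_irregularity = as.numeric(border_irregularity),
    class_label = class_label, seed = as.integer(seed)
  ), class = "synth_lesion_spec")
  validate_lesion_spec(spec)
  spec
}

validate_lesion_spec <- function(spec) {
  if (spec$border_irregularity < 0 || spec$border_irregularity > 1) {
    stop("`border_irregularity` must lie in [0, 1]", call. = FALSE)
  }
  # conservative rotation-free bound on the maximal lesion radius
  rmax <- max(spec$lesion_axes) * (1 + spec$border_irregularity) + 1
  ok <- spec$lesion_center[1] - rmax >= 1 &&
    spec$lesion_center[1] + rmax <= spec$image_height &&
    spec$lesion_center[2] - rmax >= 1 &&
    spec$lesion_center[2] + rmax <= spec$image_width
  if (!ok) {
    stop(sprintf(
      "lesion ellipse (centre %.0f,%.0f, max radius %.0f) is not fully inside the %dx%d frame",
      spec$lesion_center[1], spec$lesion_center[2], rmax,
      spec$image_height, spec$image_width), call. = FALSE)
  }
  invisible(spec)
}

#' Generate one synthetic dermoscopic image with ground truth
#'
#' Rasterizes the lesion of a [synth_lesion_spec()] by a direct per-pixel
#' inside test, so the returned lesion mask is pixel-exact. The border is the
#' ellipse radius modulated by a seeded sum of low-order sinusoidal harmonics
#' with amplitude `border_irregularity`; MEL lesions additionally darken
#' towards the core (a crude multi-tone pattern).
#'
#' @param spec a [synth_lesion_spec()].
#' @return list with `image` (H x W x 3, 0-255), `mask` (H x W in \{0,1\}) and
#'   `label` (`"MEL"`/`"BEN"`). Bit-identical for identical (spec, seed).
#' @export
generate_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "synth_lesion_spec"))
  validate_lesion_spec(spec)
  H <- spec$image_height; W <- spec$image_width
  with_seed(spec$seed, {
    th <- spec$lesion_rotation * pi / 180
    dr <- matrix(seq_len(H) - spec$lesion_center[1], H, W)
    dc <- matrix(seq_len(W) - spec$lesion_center[2], H, W, byrow = TRUE)
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    a <- spec$lesion_axes[1]; b <- spec$lesion_axes[2]
    rho <- sqrt((u / a)^2 + (v / b)^2)
    if (spec$border_irregularity > 0) {
      phi <- atan2(v / b, u / a)
      ks <- sample(3:8, 3)
      amp <- runif(3, 0.3, 1); psi <- runif(3, 0, 2 * pi)
      pert <- amp[1] * sin(ks[1] * phi + psi[1]) +
        amp[2] * sin(ks[2] * phi + psi[2]) +
        amp[3] * sin(ks[3] * phi + psi[3])
      pert <- pert / max(abs(pert))
      inside <- rho <= 1 + spec$border_irregularity * pert
    } else {
      inside <- rho <= 1
    }
    mask <- inside * 1
    # core darkening: pronounced for MEL, faint for BEN
    tone_depth <- if (spec$class_label == "MEL") 0.35 else 0.08
    tone <- 1 - tone_depth * pmax(0, 1 - rho)
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$skin_color[ch], H, W)
      plane[inside] <- (spec$lesion_color[ch] * tone)[inside]
      img[, , ch] <- plane + rnorm(H * W, 0, spec$texture_noise_sd)
    }
    list(image = as_uint8(img), mask = mask, label = spec$class_label)
  })
}

#' Draw a random lesion spec for a class
#'
#' Samples a [synth_lesion_spec()] from class-conditional ranges: MEL specs
#' have strictly darker colours and higher border irregularity than BEN specs.
#'
#' @param class_label `"MEL"` or `"BEN"`.
#' @param image_height,image_width frame size in pixels.
#' @param seed integer seed.
#' @return a `synth_lesion_spec`.
#' @export
random_lesion_spec <- function(class_label = c("BEN", "MEL"),
                               image_height = 128, image_width = 128,
                               seed = 1L) {
  class_label <- match.arg(class_label)
  with_seed(seed, {
    s <- min(image_height, image_width)
    axes <- runif(2, 0.16, 0.26) * s  # semi-axes in pixels
    irr <- if (class_label == "MEL") runif(1, 0.22, 0.40) else runif(1, 0.02, 0.10)
    col <- if (class_label == "MEL") {
      c(runif(1, 70, 110), runif(1, 40, 70), runif(1, 35, 65))
    } else {
      c(runif(1, 150, 185), runif(1, 100, 135), runif(1, 85, 120))
    }
    rmax <- max(axes) * (1 + irr) + 2
    ctr <- c(runif(1, rmax + 1, image_height - rmax),
             runif(1, rmax + 1, image_width - rmax))
    synth_lesion_spec(
      image_height = image_height, image_width = image_width,
      lesion_center = ctr, lesion_axes = axes,
      lesion_rotation = runif(1, 0, 180),
      lesion_color = col,
      skin_color = c(196, 150, 130) + runif(3, -8, 8),
      texture_noise_sd = 4,
      border_irregularity = irr,
      class_label = class_label,
      seed = derive_seed(seed, 1)
    )
  })
}

#' Hair overlay specification
#'
#' @param n_hairs number of hairs to draw.
#' @param thickness_px stroke thickness, 1-4 pixels.
#' @param hair_color dark RGB triple; drawn pixels are blended towards it and
#'   forced strictly darker than the underlying pixel.
#' @param curvature dimensionless bending of the quadratic strokes (0 =
#'   straight lines).
#' @param seed integer seed.
#' @return an object of class `hair_overlay_spec`.
#' @export
hair_overlay_spec <- function(n_hairs = 5, thickness_px = 2,
                              hair_color = c(40, 32, 28), curvature = 0.4,
                              seed = 1L) {
  if (thickness_px < 1 || thickness_px > 4) {
    stop("`thickness_px` must be between 1 and 4 pixels", call. = FALSE)
  }
  structure(list(
    n_hairs = as.integer(n_hairs), thickness_px = as.numeric(thickness_px),
    hair_color = as.numeric(hair_color), curvature = as.numeric(curvature),
    seed = as.integer(seed)
  ), class = "hair_overlay_spec")
}

# pixel offsets covering a stroke of the given thickness (no anti-aliasing)
stroke_offsets <- function(thickness) {
  r <- thickness / 2
  g <- expand.grid(dr = -2:2, dc = -2:2)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  if (nrow(g) == 0) g <- data.frame(dr = 0, dc = 0)
  g
}

#' Overlay dark curvilinear hairs on an image
#'
#' Draws seeded quadratic (Bezier) strokes 1-4 px thick without
#' anti-aliasing; every drawn pixel is recorded in the returned binary hair
#' mask and is strictly darker than the pixel it replaces (provided the input
#' pixel is not already black).
#'
#' @param image H x W x 3 array, 0-255.
#' @param spec a [hair_overlay_spec()]. `n_hairs = 0` returns the input
#'   unchanged with an empty mask.
#' @return list with `image` (hairs drawn) and `mask` (binary hair mask);
#'   the output differs from the input exactly on the mask support.
#' @export
add_hairs <- function(image, spec) {
  assert_rgb_image(image)
  stopifnot(inherits(spec, "hair_overlay_spec"))
  H <- dim(image)[1]; W <- dim(image)[2]
  mask <- matrix(0, H, W)
  if (spec$n_hairs == 0) return(list(image = image, mask = mask))
  offs <- stroke_offsets(spec$thickness_px)
  with_seed(spec$seed, {
    for (h in seq_len(spec$n_hairs)) {
      p0 <- c(runif(1, 2, H - 1), runif(1, 2, W - 1))
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 0.5, 1.1) * min(H, W)
      p2 <- p0 + len * c(sin(ang), cos(ang))
      mid <- (p0 + p2) / 2
      perp <- c(-(p2 - p0)[2], (p2 - p0)[1]) / max(1e-9, sqrt(sum((p2 - p0)^2)))
      p1 <- mid + perp * len * spec$curvature * runif(1, -1, 1)
      t <- seq(0, 1, length.out = max(16L, ceiling(3 * len)))
      pr <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
      pc <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
      for (k in seq_len(nrow(offs))) {
        rr <- round(pr) + offs$dr[k]; cc <- round(pc) + offs$dc[k]
        keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        mask[cbind(rr[keep], cc[keep])] <- 1
      }
    }
  })
  idx <- which(mask == 1)
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    v <- plane[idx]
    nv <- pmax(0, pmin(floor(0.30 * v + 0.70 * spec$hair_color[ch]), v - 1))
    plane[idx] <- nv
    out[, , ch] <- plane
  }
  list(image = out, mask = mask)
}

#' Degrade image contrast by a gamma/gain intensity remap
#'
#' Applies the monotone per-channel remap
#' `out = 255 * gain * (in / 255)^gamma`, rounded half-up and clipped to the
#' 8-bit range. `gamma = gain = 1` is the identity on integral images. Used to
#' manufacture (degraded, clean) training pairs for the contrast-restoration
#' network.
#'
#' @param image H x W x 3 array, 0-255.
#' @param gamma,gain positive scalars.
#' @return degraded image, same shape, values in \[0, 255\].
#' @export
degrade_contrast <- function(image, gamma, gain = 1) {
  assert_rgb_image(image)
  if (gamma <= 0 || gain <= 0) stop("`gamma` and `gain` must be positive", call. = FALSE)
  as_uint8(255 * gain * (image / 255)^gamma)
}

#' Create a near-duplicate of an image
#'
#' Adds seeded Gaussian pixel noise; for small `noise_sd` the result keeps a
#' Pearson correlation above 0.99 with the original, emulating repeat
#' acquisitions of the same lesion.
#'
#' @param image H x W x 3 array, 0-255.
#' @param noise_sd noise standard deviation in intensity units (>= 0).
#' @param seed integer seed.
#' @return perturbed image, same shape.
#' @export
make_near_duplicate <- function(image, noise_sd, seed = 1L) {
  assert_rgb_image(image)
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(image)
  with_seed(seed, as_uint8(image + rnorm(length(image), 0, noise_sd)))
}

#' Generate a labelled two-class synthetic dataset
#'
#' Produces `n_mel + n_ben` base images from class-conditional random specs,
#' plus `round(dup_fraction * (n_mel + n_ben))` near-duplicates flagged in the
#' index (ground truth for deduplication tests). Optionally overlays hairs
#' and/or degrades contrast, keeping the clean originals for restoration
#' tests.
#'
#' @param n_mel,n_ben class counts (>= 0).
#' @param dup_fraction fraction in `[0, 1)` of near-duplicate rows to append.
#' @param seed integer seed driving every random choice.
#' @param image_size `(height, width)` of the generated frames.
#' @param hairy logical; overlay random hairs on every base image.
#' @param degraded logical; apply a random gamma/gain contrast degradation.
#' @param hair_range range of hair counts per image when `hairy`.
#' @param thickness_range hair thickness range in pixels when `hairy`.
#' @param gamma_range,gain_range degradation parameter ranges when `degraded`.
#' @param dup_noise_sd noise for the near-duplicates (correlation > 0.99).
#' @return list with `index` (data.frame `path,label,patient_id,is_duplicate_of`),
#'   `images` (named list of final images), `masks` (lesion masks),
#'   `hair_masks` (hair ground truth, when `hairy`) and `clean_images`
#'   (hair-free, undegraded versions of the same scenes).
#' @export
generate_dataset <- function(n_mel, n_ben, dup_fraction = 0, seed = 1L,
                             image_size = c(96, 96),
                             hairy = FALSE, degraded = FALSE,
                             hair_range = c(3, 7), thickness_range = c(1, 3),
                             gamma_range = c(1.5, 2.0), gain_range = c(0.85, 1.0),
                             dup_noise_sd = 1.5) {
  stopifnot(n_mel >= 0, n_ben >= 0, dup_fraction >= 0, dup_fraction < 1)
  n <- n_mel + n_ben
  labels <- c(rep("MEL", n_mel), rep("BEN", n_ben))
  paths <- sprintf("%s_%03d.png", tolower(labels), c(seq_len(n_mel), seq_len(n_ben)))
  images <- masks <- hair_masks <- clean <- vector("list", n)
  names(images) <- names(masks) <- names(hair_masks) <- names(clean) <- paths
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    spec <- random_lesion_spec(labels[i], image_size[1], image_size[2], seed = si)
    g <- generate_lesion_image(spec)
    clean[[i]] <- g$image
    masks[[i]] <- g$mask
    img <- g$image
    if (hairy) {
      hs <- with_seed(derive_seed(si, 2), {
        hair_overlay_spec(
          n_hairs = sample(hair_range[1]:hair_range[2], 1),
          thickness_px = sample(thickness_range[1]:thickness_range[2], 1),
          seed = derive_seed(si, 3))
      })
      hh <- add_hairs(img, hs)
      img <- hh$image
      hair_masks[[i]] <- hh$mask
    } else {
      hair_masks[[i]] <- matrix(0, image_size[1], image_size[2])
    }
    if (degraded) {
      img <- with_seed(derive_seed(si, 4),
                       degrade_contrast(img, runif(1, gamma_range[1], gamma_range[2]),
                                        runif(1, gain_range[1], gain_range[2])))
    }
    images[[i]] <- img
  }
  patient <- sprintf("P%03d", ((seq_len(n) - 1) %% max(1, ceiling(n / 2))) + 1)
  index <- data.frame(path = paths, label = labels, patient_id = patient,
                      is_duplicate_of = NA_character_, stringsAsFactors = FALSE)
  n_dup <- round(dup_fraction * n)
  if (n_dup > 0) {
    src <- with_seed(derive_seed(seed, 9001), sample(n, n_dup, replace = n_dup > n))
    for (d in seq_len(n_dup)) {
      p <- sprintf("dup_%03d.png", d)
      s <- src[d]
      dup_img <- make_near_duplicate(images[[s]], dup_noise_sd,
                                     seed = derive_seed(seed, 9100 + d))
      images[[p]] <- dup_img
      masks[[p]] <- masks[[s]]
      hair_masks[[p]] <- hair_masks[[s]]
      clean[[p]] <- clean[[s]]
      index <- rbind(index, data.frame(
        path = p, label = index$label[s], patient_id = index$patient_id[s],
        is_duplicate_of = index$path[s], stringsAsFactors = FALSE))
    }
  }
  list(index = index, images = images, masks = masks,
       hair_masks = hair_masks, clean_images = clean)
}
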