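#' Atrous (dilated) convolution specification
#'
#' @param kernel_height,kernel_width odd kernel dimensions, pixels.
#' @param in_channels,out_channels channel counts.
#' @param dilation_rate integer rate `r >= 1`; taps are spaced `r` pixels
#'   apart (`r = 1` is a standard convolution).
#' @return an object of class `atrous_conv_spec`.
#' @export
atrous_conv_spec <- function(kernel_height = 3, kernel_width = 3,
                             in_channels = 1, out_channels = 1,
                             dilation_rate = 1) {
  if (dilation_rate < 1) stop("`dilation_rate` must be >= 1", call. = FALSE)
  if (kernel_height %% 2 == 0 || kernel_width %% 2 == 0) {
    stop("kernel dimensions must be odd so the anchor is centred", call. = FALSE)
  }
  structure(list(kernel_height = as.integer(kernel_height),
                 kernel_width = as.integer(kernel_width),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation_rate = as.integer(dilation_rate)),
            class = "atrous_conv_spec")
}

#' Atrous convolution of a feature map
#'
#' Computes `out(x, y, o) = sum_i sum_j sum_k I(x + i*r, y + j*r, k) *
#' K(i, j, k, o)` with centred taps, stride 1 and zero padding (output keeps
#' the spatial size). With `r = 1` this is the standard convolution;
#' equivalently, rate-`r` atrous convolution equals standard convolution with
#' a kernel zero-inflated by `r - 1` zeros between taps.
#'
#' @param feature_map H x W x C numeric array.
#' @param spec an [atrous_conv_spec()]; `in_channels` must match C.
#' @param kernel_values numeric array `kh x kw x in_channels x out_channels`.
#' @return H x W x out_channels array.
#' @export
atrous_conv2d <- function(feature_map, spec, kernel_values) {
  stopifnot(inherits(spec, "atrous_conv_spec"))
  if (length(dim(feature_map)) == 2L) {
    feature_map <- array(feature_map, dim = c(dim(feature_map), 1))
  }
  H <- dim(feature_map)[1]; W <- dim(feature_map)[2]; C <- dim(feature_map)[3]
  if (C != spec$in_channels) {
    stop(sprintf("channel mismatch: feature map has %d channels, spec expects %d",
                 C, spec$in_channels), call. = FALSE)
  }
  K <- array(kernel_values, dim = c(spec$kernel_height, spec$kernel_width,
                                    spec$in_channels, spec$out_channels))
  # weight matrix rows ordered (i, j, k) to match dc_im2col's column order
  Wm <- matrix(K, spec$kernel_height * spec$kernel_width * spec$in_channels,
               spec$out_channels)
  x <- matrix(feature_map, H * W, C)
  cols <- dc_im2col(x, 1L, H, W, spec$kernel_height, spec$kernel_width,
                    spec$dilation_rate)
  array(cols %*% Wm, dim = c(H, W, spec$out_channels))
}

#' Specification of the atrous-convolution segmentation network (ACNN)
#'
#' Sixteen 3x3 feature-extraction convolutions grouped into five blocks, each
#' followed by batch normalization and leaky ReLU; the dilation rate doubles
#' from block to block (1, 2, 4, 8, 16), there is no pooling and stride is 1
#' throughout, so the output resolution equals the input resolution. A 1x1
#' convolution head plus per-pixel softmax yields the two class maps
#' (lesion / background).
#'
#' @param input_shape `(height, width, 3)`; default 192 x 256 x 3.
#' @param n_blocks number of blocks (default 5).
#' @param layers_per_block conv layers in each block (must sum to
#'   `n_feature_layers`).
#' @param n_feature_layers total feature-extraction layers (default 16).
#' @param dilation_schedule one nondecreasing rate per block.
#' @param channels_per_block filters per block.
#' @param activation_slope leaky-ReLU slope (default 0.3).
#' @return an object of class `acnn_spec`.
#' @export
acnn_spec <- function(input_shape = c(192, 256, 3), n_blocks = 5,
                      layers_per_block = c(3, 3, 3, 3, 4),
                      n_feature_layers = 16,
                      dilation_schedule = c(1, 2, 4, 8, 16),
                      channels_per_block = c(16, 32, 48, 64, 64),
                      activation_slope = 0.3) {
  if (length(layers_per_block) != n_blocks ||
      length(dilation_schedule) != n_blocks ||
      length(channels_per_block) != n_blocks) {
    stop("`layers_per_block`, `dilation_schedule` and `channels_per_block` must have one entry per block",
         call. = FALSE)
  }
  if (sum(layers_per_block) != n_feature_layers) {
    stop(sprintf("layers per block sum to %d, expected %d feature layers",
                 sum(layers_per_block), n_feature_layers), call. = FALSE)
  }
  if (is.unsorted(dilation_schedule)) {
    stop("`dilation_schedule` must be nondecreasing", call. = FALSE)
  }
  structure(list(input_shape = as.integer(input_shape),
                 n_blocks = as.integer(n_blocks),
                 layers_per_block = as.integer(layers_per_block),
                 n_feature_layers = as.integer(n_feature_layers),
                 dilation_schedule = as.integer(dilation_schedule),
                 channels_per_block = as.integer(channels_per_block),
                 activation_slope = activation_slope),
            class = "acnn_spec")
}

#' Build the ACNN layer description
#'
#' @param spec an [acnn_spec()].
#' @return a `network_spec` with 16 feature-extraction convolutions in 5
#'   blocks, a 1x1 two-class head and a per-pixel softmax.
#' @export
build_acnn <- function(spec = acnn_spec()) {
  stopifnot(inherits(spec, "acnn_spec"))
  layers <- list()
  cin <- spec$input_shape[3]
  for (b in seq_len(spec$n_blocks)) {
    for (l in seq_len(spec$layers_per_block[b])) {
      cout <- spec$channels_per_block[b]
      layers <- c(layers, list(
        layer_conv(cin, cout, c(3, 3), spec$dilation_schedule[b]),
        layer_batch_norm(cout),
        layer_leaky_relu(spec$activation_slope)))
      cin <- cout
    }
  }
  layers <- c(layers, list(layer_conv(cin, 2, c(1, 1), 1), layer_softmax()))
  new_network_spec(layers, spec$input_shape)
}

#' ACNN training configuration
#'
#' Defaults: batch size 16, learning rate 0.01, L2 regularization 0.005,
#' momentum 0.9, 30 epochs, weighted cross-entropy loss, SGDM optimizer.
#'
#' @param batch_size,learning_rate,l2,momentum,epochs training
#'   hyperparameters.
#' @return an object of class `acnn_train_config`.
#' @export
acnn_train_config <- function(batch_size = 16, learning_rate = 0.01,
                              l2 = 0.005, momentum = 0.9, epochs = 30) {
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 l2 = l2, momentum = momentum, epochs = epochs,
                 loss = "weighted cross-entropy", optimizer = "SGDM"),
            class = "acnn_train_config")
}

#' Instantiate an untrained ACNN model
#'
#' @param spec an [acnn_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `acnn_model`.
#' @export
acnn_model <- function(spec = acnn_spec(), seed = 1L) {
  net <- build_acnn(spec)
  ini <- nn_init_params(net, seed)
  structure(list(spec = spec, net = net, params = ini$params,
                 buffers = ini$buffers, trained = FALSE, history = numeric(0)),
            class = "acnn_model")
}

# one-hot pixel targets: column 1 = background, column 2 = lesion
mask_onehot <- function(masks) {
  v <- unlist(lapply(masks, as.vector))
  cbind(1 - v, v)
}

#' Train the segmentation network
#'
#' Weighted cross-entropy over pixels with class weights set to inverse pixel
#' frequency on the training masks, optimized by SGDM with the configuration
#' defaults. Seeded and deterministic; learning rate 0 leaves the weights
#' unchanged.
#'
#' @param model an [acnn_model()].
#' @param images list of H x W x 3 arrays matching the model input shape.
#' @param masks list of binary H x W lesion masks aligned to `images`.
#' @param cfg an [acnn_train_config()].
#' @param seed integer seed.
#' @return the trained model; `$history` holds the mean training loss per
#'   epoch, `$class_weights` the background/lesion weights used.
#' @export
train_acnn <- function(model, images, masks, cfg = acnn_train_config(), seed = 1L) {
  stopifnot(inherits(model, "acnn_model"), length(images) == length(masks))
  H <- model$spec$input_shape[1]; W <- model$spec$input_shape[2]
  for (m in masks) {
    if (!all(m %in% c(0, 1))) stop("mask values outside {0, 1}", call. = FALSE)
  }
  xs <- lapply(images, function(im) {
    stopifnot(all(dim(im)[1:2] == c(H, W)))
    matrix(im, H * W, 3) / 255
  })
  n_les <- sum(unlist(lapply(masks, sum)))
  n_tot <- length(masks) * H * W
  n_bg <- n_tot - n_les
  if (n_les == 0 || n_bg == 0) stop("training masks must contain both classes", call. = FALSE)
  w <- n_tot / (2 * c(n_bg, n_les))  # inverse pixel frequency
  vel <- sgdm_init_state(model$params)
  history <- numeric(cfg$epochs)
  with_seed(derive_seed(seed, 31), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(xs))
      losses <- numeric(0)
      for (s in seq(1, length(ord), by = cfg$batch_size)) {
        ids <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        B <- length(ids)
        x <- do.call(rbind, xs[ids])
        T_ <- mask_onehot(masks[ids])
        fw <- nn_forward(model$net, model$params, model$buffers, x, B, training = TRUE)
        model$buffers <- fw$buffers
        losses <- c(losses, cross_entropy_loss(fw$out, T_, w))
        dlogits <- ce_grad_logits(fw$out, T_, w)
        grads <- nn_backward(model$net, model$params, fw$caches, dlogits, B)
        up <- sgdm_update_all(model$params, grads, vel, cfg$learning_rate,
                              cfg$momentum, cfg$l2)
        model$params <- up$params
        vel <- up$vel
      }
      history[ep] <- mean(losses)
    }
  })
  model$history <- c(model$history, history)
  model$class_weights <- w
  model$trained <- TRUE
  model
}

#' Segment a lesion with a trained ACNN
#'
#' The image is resized to the model input shape, classified per pixel by
#' argmax of the softmax output, and the binary mask is resized back to the
#' original frame (nearest neighbour).
#'
#' @param model a trained [acnn_model()].
#' @param image H x W x 3 array, 0-255.
#' @return binary H x W lesion mask.
#' @export
segment <- function(model, image) {
  stopifnot(inherits(model, "acnn_model"))
  assert_rgb_image(image)
  H <- model$spec$input_shape[1]; W <- model$spec$input_shape[2]
  orig <- dim(image)[1:2]
  im <- if (all(orig == c(H, W))) image else resize_image(image, H, W)
  x <- matrix(im, H * W, 3) / 255
  out <- nn_forward(model$net, model$params, model$buffers, x, 1L,
                    training = FALSE)$out
  mask <- matrix((out[, 2] > out[, 1]) * 1, H, W)
  if (!all(orig == c(H, W))) mask <- resize_image(mask, orig[1], orig[2], mask = TRUE)
  mask
}

#' Crop an image to the lesion region of interest
#'
#' Takes the bounding box of the mask, expands it by `margin` pixels, clips
#' it to the frame, and zeroes every pixel outside the mask within the crop.
#' An empty mask returns the full image with a warning.
#'
#' @param image H x W x 3 array.
#' @param mask binary H x W matrix aligned to the image.
#' @param margin bounding-box expansion in pixels.
#' @return cropped image array.
#' @export
crop_roi <- function(image, mask, margin = 0) {
  assert_rgb_image(image)
  assert_mask(mask, image)
  if (sum(mask) == 0) {
    warning("empty mask: returning the full image")
    return(image)
  }
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  r0 <- max(1, rr[1] - margin); r1 <- min(nrow(mask), rr[2] + margin)
  c0 <- max(1, cc[1] - margin); c1 <- min(ncol(mask), cc[2] + margin)
  out <- image[r0:r1, c0:c1, , drop = FALSE]
  sub <- mask[r0:r1, c0:c1]
  for (ch in 1:3) out[, , ch] <- out[, , ch] * sub
  out
}
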