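#' Specification of one multiscale residual aggregation block (MRAB)
#'
#' Each context module of the contrast-restoration network holds one dilated
#' 3x3 convolution, batch normalization, a leaky-ReLU activation, and an
#' adaptive-normalization combination of the identity and normalized branches
#' `out = mu * x + lambda * BN(conv(x))` with learnable scalars `mu`, `lambda`
#' (initialized to 1 and 0, so a freshly built block is the identity).
#'
#' @param dilation_rate one of 2, 4, 6, 8, 16, 32, 64, 128.
#' @param n_filters number of convolution filters (default 32).
#' @param kernel kernel size (default 3x3).
#' @return an object of class `mrab_spec`.
#' @export
mrab_spec <- function(dilation_rate, n_filters = 32, kernel = c(3, 3)) {
  allowed <- c(2, 4, 6, 8, 16, 32, 64, 128)
  if (!dilation_rate %in% allowed) {
    stop(sprintf("invalid MRAB dilation rate %s; must be one of {%s}",
                 dilation_rate, paste(allowed, collapse = ",")), call. = FALSE)
  }
  if (n_filters <= 0) stop("`n_filters` must be positive", call. = FALSE)
  structure(list(dilation_rate = as.integer(dilation_rate),
                 n_filters = as.integer(n_filters), kernel = as.integer(kernel)),
            class = "mrab_spec")
}

#' Specification of the multiscale context aggregation network (MCAN)
#'
#' Eight MRABs chained in order of increasing dilation rate
#' (2, 4, 6, 8, 16, 32, 64, 128 by default), preceded by a 3x3 input
#' convolution that lifts the RGB input to `n_filters` channels and followed
#' by a 1x1 regression convolution back to 3 channels. Images are processed
#' as square patches (`patch_size`).
#'
#' @param n_mrab number of context modules (default 8).
#' @param patch_size square patch edge in pixels (default 256).
#' @param n_filters filters per block (default 32).
#' @param dilation_rates one rate per MRAB, from the allowed set.
#' @return an object of class `mcan_spec`.
#' @export
mcan_spec <- function(n_mrab = 8, patch_size = 256, n_filters = 32,
                      dilation_rates = c(2, 4, 6, 8, 16, 32, 64, 128)[seq_len(n_mrab)]) {
  if (length(dilation_rates) != n_mrab) {
    stop("`dilation_rates` must supply one rate per MRAB", call. = FALSE)
  }
  mrabs <- lapply(dilation_rates, mrab_spec, n_filters = n_filters)
  structure(list(n_mrab = as.integer(n_mrab), patch_size = as.integer(patch_size),
                 n_filters = as.integer(n_filters), mrabs = mrabs),
            class = "mcan_spec")
}

#' Build the MCAN layer description
#'
#' Returns the declarative layer list (a `network_spec`) from which parameter
#' counts and receptive fields are computable.
#'
#' @param spec an [mcan_spec()].
#' @return a `network_spec`.
#' @export
build_mcan <- function(spec = mcan_spec()) {
  stopifnot(inherits(spec, "mcan_spec"))
  f <- spec$n_filters
  layers <- list(layer_conv(3, f, c(3, 3), 1), layer_batch_norm(f),
                 layer_leaky_relu(0.3))
  for (m in spec$mrabs) {
    layers <- c(layers, list(
      layer_conv(f, m$n_filters, m$kernel, m$dilation_rate),
      layer_batch_norm(m$n_filters),
      layer_leaky_relu(0.3),
      layer_adaptive_norm()))
  }
  layers <- c(layers, list(layer_conv(f, 3, c(1, 1), 1)))
  new_network_spec(layers, c(spec$patch_size, spec$patch_size, 3))
}

#' Instantiate an untrained MCAN model
#'
#' @param spec an [mcan_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `mcan_model`.
#' @export
mcan_model <- function(spec = mcan_spec(), seed = 1L) {
  f <- spec$n_filters
  with_seed(seed, {
    init_conv <- function(k2cin, cout) {
      list(W = matrix(rnorm(k2cin * cout, 0, sqrt(2 / k2cin)), k2cin, cout),
           b = numeric(cout))
    }
    params <- list(
      entry = list(conv = init_conv(9 * 3, f),
                   bn = list(gamma = rep(1, f), beta = rep(0, f))),
      blocks = lapply(spec$mrabs, function(m) list(
        conv = init_conv(9 * f, m$n_filters),
        bn = list(gamma = rep(1, m$n_filters), beta = rep(0, m$n_filters)),
        an = list(mu = 1, lambda = 0))),
      head = init_conv(f, 3))
  })
  buffers <- list(entry = list(mean = rep(0, f), var = rep(1, f)),
                  blocks = lapply(spec$mrabs, function(m)
                    list(mean = rep(0, m$n_filters), var = rep(1, m$n_filters))))
  structure(list(spec = spec, params = params, buffers = buffers,
                 trained = FALSE, history = numeric(0)),
            class = "mcan_model")
}

# forward pass on a (B*P*P) x 3 matrix of [0,1] intensities
mcan_forward <- function(model, x, B, P, training = FALSE) {
  pr <- model$params; bu <- model$buffers
  slope <- 0.3
  cache <- list()
  l_entry <- layer_conv(3, model$spec$n_filters, c(3, 3), 1)
  cache$x_in <- x
  h <- conv_fw(x, B, P, P, pr$entry$conv, l_entry)
  rb <- bn_fw(h, pr$entry$bn, bu$entry, training)
  bu$entry <- rb$buf; cache$entry_bn <- rb$cache
  ra <- lrelu_fw(rb$y, slope)
  cache$entry_neg <- ra$neg
  cur <- ra$y
  cache$blocks <- vector("list", length(pr$blocks))
  for (i in seq_along(pr$blocks)) {
    m <- model$spec$mrabs[[i]]
    l <- layer_conv(model$spec$n_filters, m$n_filters, m$kernel, m$dilation_rate)
    bc <- list(x_prev = cur)
    h1 <- conv_fw(cur, B, P, P, pr$blocks[[i]]$conv, l)
    rb <- bn_fw(h1, pr$blocks[[i]]$bn, bu$blocks[[i]], training)
    bu$blocks[[i]] <- rb$buf; bc$bn <- rb$cache
    ra <- lrelu_fw(rb$y, slope)
    bc$neg <- ra$neg; bc$h3 <- ra$y
    cur <- pr$blocks[[i]]$an$mu * cur + pr$blocks[[i]]$an$lambda * ra$y
    cache$blocks[[i]] <- bc
  }
  cache$x_last <- cur
  y <- conv_fw(cur, B, P, P, pr$head, layer_conv(model$spec$n_filters, 3, c(1, 1), 1))
  list(y = y, cache = cache, buffers = bu)
}

mcan_backward <- function(model, cache, dy, B, P) {
  pr <- model$params
  f <- model$spec$n_filters
  slope <- 0.3
  g <- list()
  hb <- conv_bw(cache$x_last, dy, B, P, P, pr$head, layer_conv(f, 3, c(1, 1), 1))
  g$head <- hb$grads
  dcur <- hb$dx
  g$blocks <- vector("list", length(pr$blocks))
  for (i in rev(seq_along(pr$blocks))) {
    m <- model$spec$mrabs[[i]]
    bc <- cache$blocks[[i]]
    an <- pr$blocks[[i]]$an
    dmu <- sum(dcur * bc$x_prev)
    dlambda <- sum(dcur * bc$h3)
    dh3 <- an$lambda * dcur
    dh2 <- lrelu_bw(dh3, bc$neg, slope)
    rb <- bn_bw(dh2, bc$bn, pr$blocks[[i]]$bn)
    cb <- conv_bw(bc$x_prev, rb$dx, B, P, P, pr$blocks[[i]]$conv,
                  layer_conv(f, m$n_filters, m$kernel, m$dilation_rate))
    g$blocks[[i]] <- list(conv = cb$grads, bn = rb$grads,
                          an = list(mu = dmu, lambda = dlambda))
    dcur <- an$mu * dcur + cb$dx
  }
  da <- lrelu_bw(dcur, cache$entry_neg, slope)
  rb <- bn_bw(da, cache$entry_bn, pr$entry$bn)
  cb <- conv_bw(cache$x_in, rb$dx, B, P, P, pr$entry$conv, layer_conv(3, f, c(3, 3), 1))
  g$entry <- list(conv = cb$grads, bn = rb$grads)
  g
}

# flatten nested param/grad lists for the optimizer
mcan_update <- function(params, grads, vel, lr, momentum, l2) {
  upd <- function(p, g, v) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) {
        r <- upd(p[[nm]], g[[nm]], v[[nm]])
        p[[nm]] <- r$p; v[[nm]] <- r$v
      } else {
        gg <- g[[nm]]
        if (nm == "W" && l2 > 0) gg <- gg + l2 * p[[nm]]
        st <- sgdm_step(p[[nm]], gg, v[[nm]], lr, momentum)
        p[[nm]] <- st$theta; v[[nm]] <- st$velocity
      }
    }
    list(p = p, v = v)
  }
  r <- upd(params, grads, vel)
  list(params = r$p, vel = r$v)
}

zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0

default_degradation_sampler <- function(seed = 1L) {
  # gamma down to 1 includes the identity, so the trained network also learns
  # to leave already-clean inputs approximately unchanged
  function(image, k) {
    with_seed(derive_seed(seed, k),
              degrade_contrast(image, runif(1, 1.0, 2.0), runif(1, 0.85, 1.0)))
  }
}

#' Split an image into square patches / reassemble it
#'
#' The image is padded by edge replication to a multiple of `patch_size`;
#' `stitch_patches()` inverts the tiling exactly on the original extent.
#'
#' @param image H x W x 3 array.
#' @param patch_size square patch edge, pixels.
#' @param patches list produced by `extract_patches()`.
#' @param layout the `$layout` element produced by `extract_patches()`.
#' @return `extract_patches()`: list with `patches` (list of arrays) and
#'   `layout`; `stitch_patches()`: the reassembled H x W x 3 image.
#' @export
extract_patches <- function(image, patch_size) {
  assert_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  P <- patch_size
  nr <- ceiling(H / P); nc <- ceiling(W / P)
  ridx <- pmin(seq_len(nr * P), H)  # edge replication
  cidx <- pmin(seq_len(nc * P), W)
  padded <- image[ridx, cidx, , drop = FALSE]
  patches <- vector("list", nr * nc)
  k <- 1
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      patches[[k]] <- padded[((i - 1) * P + 1):(i * P),
                             ((j - 1) * P + 1):(j * P), , drop = FALSE]
      k <- k + 1
    }
  }
  list(patches = patches, layout = list(H = H, W = W, nr = nr, nc = nc, P = P))
}

#' @rdname extract_patches
#' @export
stitch_patches <- function(patches, layout) {
  P <- layout$P
  out <- array(0, dim = c(layout$nr * P, layout$nc * P, 3))
  k <- 1
  for (j in seq_len(layout$nc)) {
    for (i in seq_len(layout$nr)) {
      out[((i - 1) * P + 1):(i * P), ((j - 1) * P + 1):(j * P), ] <- patches[[k]]
      k <- k + 1
    }
  }
  out[seq_len(layout$H), seq_len(layout$W), , drop = FALSE]
}

#' Train the contrast-restoration network
#'
#' Trains on (degraded, clean) patch pairs manufactured from clean images by
#' a seeded degradation sampler (random gamma/gain remaps by default), with a
#' mean-squared-error regression loss at the output layer and SGDM updates.
#' Deterministic given `seed`; zero epochs returns the model unchanged.
#'
#' @param model an [mcan_model()].
#' @param clean_images list of H x W x 3 arrays with natural contrast.
#' @param degradation_sampler `function(image, k)` returning a degraded copy;
#'   default applies gamma in \[1.5, 2\] and gain in \[0.85, 1\].
#' @param epochs,learning_rate,momentum,batch_size training hyperparameters.
#' @param seed integer seed for shuffling and the default sampler.
#' @return the trained model; `$history` holds the mean training loss per
#'   epoch.
#' @export
train_mcan <- function(model, clean_images, degradation_sampler = NULL,
                       epochs = 30, learning_rate = 0.01, momentum = 0.9,
                       batch_size = 8, seed = 1L) {
  stopifnot(inherits(model, "mcan_model"))
  if (length(clean_images) == 0) stop("empty training set", call. = FALSE)
  if (epochs == 0) return(model)
  if (is.null(degradation_sampler)) degradation_sampler <- default_degradation_sampler(seed)
  P <- model$spec$patch_size
  tiles <- list()
  for (im in clean_images) {
    stopifnot(dim(im)[1] >= 1)
    tiles <- c(tiles, extract_patches(im, P)$patches)
  }
  clean_m <- lapply(tiles, function(p) matrix(p, P * P, 3) / 255)
  deg_m <- lapply(seq_along(tiles), function(k)
    matrix(degradation_sampler(tiles[[k]], k), P * P, 3) / 255)
  vel <- zero_like(model$params)
  history <- numeric(epochs)
  with_seed(derive_seed(seed, 77), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(tiles))
      losses <- numeric(0)
      for (s in seq(1, length(ord), by = batch_size)) {
        ids <- ord[s:min(s + batch_size - 1, length(ord))]
        B <- length(ids)
        x <- do.call(rbind, deg_m[ids])
        t_ <- do.call(rbind, clean_m[ids])
        fw <- mcan_forward(model, x, B, P, training = TRUE)
        model$buffers <- fw$buffers
        resid <- fw$y - t_
        losses <- c(losses, mean(resid^2))
        dy <- 2 * resid / length(resid)
        g <- mcan_backward(model, fw$cache, dy, B, P)
        up <- mcan_update(model$params, g, vel, learning_rate, momentum, l2 = 0)
        model$params <- up$params
        vel <- up$vel
      }
      history[ep] <- mean(losses)
    }
  })
  model$history <- c(model$history, history)
  model$trained <- TRUE
  model
}

#' Restore contrast of an image with a trained MCAN
#'
#' The image is tiled into the model's patch size (edge-replicated padding),
#' each patch is passed through the network, and the output is stitched back
#' and clipped to the 8-bit range. Deterministic given the weights.
#'
#' @param model an [mcan_model()] (a warning is issued if untrained).
#' @param image H x W x 3 array, 0-255.
#' @return enhanced image, same shape, values in \[0, 255\].
#' @export
enhance <- function(model, image) {
  stopifnot(inherits(model, "mcan_model"))
  assert_rgb_image(image)
  if (!model$trained) warning("enhancing with an untrained contrast model")
  P <- model$spec$patch_size
  ep <- extract_patches(image, P)
  B <- length(ep$patches)
  x <- do.call(rbind, lapply(ep$patches, function(p) matrix(p, P * P, 3) / 255))
  y <- mcan_forward(model, x, B, P, training = FALSE)$y
  outp <- lapply(seq_len(B), function(b)
    array(clip(y[((b - 1) * P * P + 1):(b * P * P), ], 0, 1) * 255, dim = c(P, P, 3)))
  as_uint8(stitch_patches(outp, ep$layout))
}
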