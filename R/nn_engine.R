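# Minimal CNN engine used by the contrast, segmentation and classification
# networks. Feature maps travel as (B*H*W) x C matrices (column-major pixels
# within an image, images stacked; see src/conv_ops.cpp); dense layers switch
# to B x F. All convolutions are stride 1 with centred kernels and zero
# padding, so spatial size is preserved; pooling is the only downsampler.

# ---- layer descriptors -----------------------------------------------------

layer_conv <- function(in_channels, out_channels, kernel = c(3, 3), dilation = 1) {
  list(kind = "conv", kernel = as.integer(kernel),
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels), dilation = as.integer(dilation))
}
layer_batch_norm <- function(features) list(kind = "batch_norm", features = as.integer(features))
layer_leaky_relu <- function(slope = 0.3) list(kind = "leaky_relu", slope = slope)
layer_max_pool <- function(size = 2) list(kind = "max_pool", size = as.integer(size))
layer_flatten <- function() list(kind = "flatten")
layer_dense <- function(in_features, out_features) {
  list(kind = "dense", in_features = as.integer(in_features),
       out_features = as.integer(out_features))
}
layer_softmax <- function() list(kind = "softmax")
layer_adaptive_norm <- function() list(kind = "adaptive_norm")

new_network_spec <- function(layers, input_shape) {
  structure(list(layers = layers, input_shape = input_shape),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> input %s, %d layers\n",
              paste(x$input_shape, collapse = "x"), length(x$layers)))
  for (l in x$layers) {
    extra <- switch(l$kind,
      conv = sprintf("%dx%d, %d->%d, rate %d", l$kernel[1], l$kernel[2],
                     l$in_channels, l$out_channels, l$dilation),
      dense = sprintf("%d->%d", l$in_features, l$out_features),
      batch_norm = sprintf("%d features", l$features),
      leaky_relu = sprintf("slope %.2f", l$slope),
      "")
    cat(sprintf("  %-14s %s\n", l$kind, extra))
  }
  invisible(x)
}

#' Receptive field of each convolution layer
#'
#' Standard recurrence for stride-1 dilated convolutions:
#' `rf_l = rf_(l-1) + (k - 1) * rate_l`.
#'
#' @param net a `network_spec`.
#' @return integer vector of receptive field sizes after each conv layer.
#' @export
receptive_field <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  rf <- 1L; out <- integer(0)
  for (l in net$layers) {
    if (l$kind == "conv") {
      rf <- rf + (l$kernel[1] - 1L) * l$dilation
      out <- c(out, rf)
    } else if (l$kind == "max_pool") {
      rf <- rf + l$size - 1L  # ignoring stride accounting; conv layers dominate
    }
  }
  out
}

# ---- parameter init --------------------------------------------------------

nn_init_params <- function(spec, seed = 1L) {
  with_seed(seed, {
    params <- vector("list", length(spec$layers))
    buffers <- vector("list", length(spec$layers))
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]
      params[[i]] <- switch(l$kind,
        conv = {
          fan_in <- prod(l$kernel) * l$in_channels
          list(W = matrix(rnorm(fan_in * l$out_channels, 0, sqrt(2 / fan_in)),
                          fan_in, l$out_channels),
               b = numeric(l$out_channels))
        },
        dense = list(
          W = matrix(rnorm(l$in_features * l$out_features, 0,
                           sqrt(2 / l$in_features)),
                     l$in_features, l$out_features),
          b = numeric(l$out_features)),
        batch_norm = list(gamma = rep(1, l$features), beta = rep(0, l$features)),
        adaptive_norm = list(mu = 1, lambda = 0),
        NULL)
      if (l$kind == "batch_norm") {
        buffers[[i]] <- list(mean = rep(0, l$features), var = rep(1, l$features))
      }
    }
    list(params = params, buffers = buffers)
  })
}

# ---- layer primitives ------------------------------------------------------

conv_fw <- function(x, B, H, W, p, l) {
  cols <- dc_im2col(x, B, H, W, l$kernel[1], l$kernel[2], l$dilation)
  sweep(cols %*% p$W, 2, p$b, "+")
}

conv_bw <- function(x, dy, B, H, W, p, l) {
  cols <- dc_im2col(x, B, H, W, l$kernel[1], l$kernel[2], l$dilation)
  dW <- crossprod(cols, dy)
  db <- colSums(dy)
  dx <- dc_col2im(dy %*% t(p$W), B, H, W, l$in_channels,
                  l$kernel[1], l$kernel[2], l$dilation)
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_fw <- function(x, p, buf, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    m <- colMeans(x)
    xc <- sweep(x, 2, m, "-")
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, invstd, "*")
    buf$mean <- (1 - momentum) * buf$mean + momentum * m
    buf$var <- (1 - momentum) * buf$var + momentum * v
  } else {
    invstd <- 1 / sqrt(buf$var + eps)
    xhat <- sweep(sweep(x, 2, buf$mean, "-"), 2, invstd, "*")
  }
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(y = y, cache = list(xhat = xhat, invstd = invstd), buf = buf)
}

bn_bw <- function(dy, cache, p) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, p$gamma, "*")
  mh <- colMeans(dxhat)
  mxh <- colMeans(dxhat * xhat)
  # dx = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  dx <- sweep(dxhat, 2, mh, "-") - sweep(xhat, 2, mxh, "*")
  dx <- sweep(dx, 2, cache$invstd, "*")
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

lrelu_fw <- function(x, slope) {
  y <- x
  neg <- x < 0
  y[neg] <- slope * x[neg]
  list(y = y, neg = neg)
}

lrelu_bw <- function(dy, neg, slope) {
  dx <- dy
  dx[neg] <- slope * dy[neg]
  dx
}

pool_indices <- function(B, H, W) {
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  Hp <- H %/% 2; Wp <- W %/% 2
  b <- rep(seq_len(B), each = Hp * Wp)
  r <- rep(rep(seq_len(Hp), Wp), B)
  cc <- rep(rep(seq_len(Wp), each = Hp), B)
  i11 <- (b - 1) * H * W + (2 * cc - 2) * H + (2 * r - 1)
  list(i11, i11 + 1L, i11 + H, i11 + H + 1L)
}

pool_fw <- function(x, B, H, W) {
  idx <- pool_indices(B, H, W)
  cur <- x[idx[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), ncol(cur))
  for (k in 2:4) {
    xk <- x[idx[[k]], , drop = FALSE]
    upd <- xk > cur
    cur[upd] <- xk[upd]
    arg[upd] <- k
  }
  list(y = cur, arg = arg, idx = idx)
}

pool_bw <- function(dy, cache, B, H, W, C) {
  dx <- matrix(0, B * H * W, C)
  for (k in 1:4) {
    dx[cache$idx[[k]], ] <- dy * (cache$arg == k)
  }
  dx
}

flatten_fw <- function(x, B, H, W) {
  a <- array(x, dim = c(H * W, B, ncol(x)))
  t(matrix(aperm(a, c(1, 3, 2)), H * W * ncol(x), B))
}

flatten_bw <- function(dy, B, H, W, C) {
  a <- array(t(dy), dim = c(H * W, C, B))
  matrix(aperm(a, c(1, 3, 2)), B * H * W, C)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- sequential forward/backward ------------------------------------------

# x: (B*H*W) x C input. Returns output, per-layer caches and updated buffers.
nn_forward <- function(spec, params, buffers, x, B, training = FALSE) {
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  caches <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv") {
      caches[[i]] <- list(x = x, H = H, W = W)
      x <- conv_fw(x, B, H, W, params[[i]], l)
    } else if (l$kind == "batch_norm") {
      r <- bn_fw(x, params[[i]], buffers[[i]], training)
      caches[[i]] <- r$cache
      buffers[[i]] <- r$buf
      x <- r$y
    } else if (l$kind == "leaky_relu") {
      r <- lrelu_fw(x, l$slope)
      caches[[i]] <- list(neg = r$neg)
      x <- r$y
    } else if (l$kind == "max_pool") {
      r <- pool_fw(x, B, H, W)
      caches[[i]] <- list(arg = r$arg, idx = r$idx, H = H, W = W, C = ncol(x))
      x <- r$y
      H <- H %/% 2; W <- W %/% 2
    } else if (l$kind == "flatten") {
      caches[[i]] <- list(H = H, W = W, C = ncol(x))
      x <- flatten_fw(x, B, H, W)
    } else if (l$kind == "dense") {
      caches[[i]] <- list(x = x)
      x <- sweep(x %*% params[[i]]$W, 2, params[[i]]$b, "+")
    } else if (l$kind == "softmax") {
      x <- softmax_rows(x)
    } else {
      stop(sprintf("unsupported layer kind in sequential network: %s", l$kind))
    }
  }
  list(out = x, caches = caches, buffers = buffers)
}

# dout is the gradient at the *logits* (the layer feeding the final softmax);
# the softmax layer itself is fused with the loss.
nn_backward <- function(spec, params, caches, dout, B) {
  grads <- vector("list", length(spec$layers))
  layers <- spec$layers
  start <- length(layers)
  if (layers[[start]]$kind == "softmax") start <- start - 1L
  dy <- dout
  for (i in seq(start, 1)) {
    l <- layers[[i]]
    if (l$kind == "conv") {
      cb <- conv_bw(caches[[i]]$x, dy, B, caches[[i]]$H, caches[[i]]$W,
                    params[[i]], l)
      grads[[i]] <- cb$grads
      dy <- cb$dx
    } else if (l$kind == "batch_norm") {
      r <- bn_bw(dy, caches[[i]], params[[i]])
      grads[[i]] <- r$grads
      dy <- r$dx
    } else if (l$kind == "leaky_relu") {
      dy <- lrelu_bw(dy, caches[[i]]$neg, l$slope)
    } else if (l$kind == "max_pool") {
      dy <- pool_bw(dy, caches[[i]], B, caches[[i]]$H, caches[[i]]$W, caches[[i]]$C)
    } else if (l$kind == "flatten") {
      dy <- flatten_bw(dy, B, caches[[i]]$H, caches[[i]]$W, caches[[i]]$C)
    } else if (l$kind == "dense") {
      grads[[i]] <- list(W = crossprod(caches[[i]]$x, dy), b = colSums(dy))
      dy <- tcrossprod(dy, params[[i]]$W)
    }
  }
  grads
}

# ---- SGDM ------------------------------------------------------------------

#' One step of stochastic gradient descent with momentum
#'
#' Classical momentum: `v' = momentum * v - lr * grad; theta' = theta + v'`.
#' With `momentum = 0` this reduces to plain gradient descent.
#'
#' @param theta parameter vector/matrix.
#' @param grad gradient of the loss at `theta`, same shape.
#' @param velocity accumulated velocity, same shape (0 at the first step).
#' @param lr learning rate (alpha > 0).
#' @param momentum momentum coefficient (gamma in `[0, 1)`).
#' @return list with updated `theta` and `velocity`.
#' @export
sgdm_step <- function(theta, grad, velocity, lr, momentum = 0) {
  stopifnot(identical(dim(theta), dim(grad)) || length(theta) == length(grad))
  velocity <- momentum * velocity - lr * grad
  # keep theta's (lack of) names: gradients may carry incidental dimnames
  if (is.matrix(theta)) dimnames(velocity) <- dimnames(theta)
  else names(velocity) <- names(theta)
  list(theta = theta + velocity, velocity = velocity)
}

sgdm_init_state <- function(params) {
  lapply(params, function(p) if (is.null(p)) NULL else lapply(p, function(x) x * 0))
}

# L2 decay applies to weight matrices only (W), not biases or normalization
# scales, matching common practice.
sgdm_update_all <- function(params, grads, vel, lr, momentum, l2) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      if (nm == "W" && l2 > 0) g <- g + l2 * params[[i]][[nm]]
      st <- sgdm_step(params[[i]][[nm]], g, vel[[i]][[nm]], lr, momentum)
      params[[i]][[nm]] <- st$theta
      vel[[i]][[nm]] <- st$velocity
    }
  }
  list(params = params, vel = vel)
}

# ---- losses ----------------------------------------------------------------

#' Weighted cross-entropy loss
#'
#' `loss = -(1/N) * sum_i sum_j w_j * T_ij * log(P_ij)` for N rows
#' (samples or pixels) and K classes, with per-class weights `w`.
#' Probabilities exactly 0 at a target position are clamped at 1e-12 with a
#' warning.
#'
#' @param probabilities N x K matrix, each row on the probability simplex.
#' @param targets N x K one-hot matrix.
#' @param class_weights length-K nonnegative weights (default all 1).
#' @return scalar loss (nonnegative for nonnegative weights).
#' @export
cross_entropy_loss <- function(probabilities, targets, class_weights = NULL) {
  P <- as.matrix(probabilities); T_ <- as.matrix(targets)
  stopifnot(identical(dim(P), dim(T_)))
  if (is.null(class_weights)) class_weights <- rep(1, ncol(P))
  if (any(P[T_ == 1] == 0)) {
    warning("zero predicted probability at a target; clamped at 1e-12")
    P <- pmax(P, 1e-12)
  }
  -sum(sweep(T_ * log(pmax(P, 1e-12)), 2, class_weights, "*")) / nrow(P)
}

# gradient of the weighted CE at the logits, fused through the softmax
ce_grad_logits <- function(P, T_, class_weights) {
  w_row <- as.vector(T_ %*% class_weights)
  (P - T_) * w_row / nrow(P)
}

#' Leaky rectified linear unit
#'
#' `x` for `x >= 0`, `slope * x` for `x < 0`.
#'
#' @param x numeric vector/array.
#' @param slope scalar multiplier for negative inputs (default 0.3).
#' @return transformed values, same shape.
#' @export
leaky_relu <- function(x, slope = 0.3) {
  ifelse(x < 0, x * slope, x)
}
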