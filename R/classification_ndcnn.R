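#' Specification of the compact classification network (N-DCNN)
#'
#' Eleven blocks: a first convolution block (8 kernels of 3x3), three
#' convolution groups repeated 2, 4 and 2 times, a fully connected block and
#' the softmax output block. Every convolution block is conv -> batch
#' normalization -> leaky ReLU (slope 0.3); a 2x2 max-pool follows the first
#' block and each group. The default channel schedule is a squeeze/expand
#' (bottleneck) pattern `8 | 32,32 | 960,32,960,32 | 960,64` with a 320-unit
#' fully connected layer, which keeps the network lightweight: about 3.27
#' million learnable parameters and 3,080 convolution kernels.
#'
#' @param input_shape `(height, width, 3)`; default 128 x 128 x 3. Height and
#'   width must be divisible by 16 (four pooling stages).
#' @param first_conv filters in the first block (default 8, kernels 3x3).
#' @param block_repeats repeats of the three groups (default `c(2, 4, 2)`).
#' @param channel_schedule filters of the 8 grouped conv blocks, in order.
#' @param fc_hidden units of the fully connected block.
#' @param activation_slope leaky-ReLU slope `s` (default 0.3).
#' @param n_classes number of output classes (2: MEL, BEN).
#' @param enforce_budget check the default parameter budget (3.0-3.6 million
#'   learnable parameters, 2,800-3,400 kernels) when building; reduced
#'   desk-scale configurations set this to `FALSE`.
#' @return an object of class `ndcnn_spec`.
#' @export
ndcnn_spec <- function(input_shape = c(128, 128, 3),
                       first_conv = 8,
                       block_repeats = c(2, 4, 2),
                       channel_schedule = c(32, 32, 960, 32, 960, 32, 960, 64),
                       fc_hidden = 320,
                       activation_slope = 0.3,
                       n_classes = 2,
                       enforce_budget = missing(channel_schedule) &&
                         missing(fc_hidden) && missing(input_shape)) {
  if (length(channel_schedule) != sum(block_repeats)) {
    stop("`channel_schedule` must supply one width per grouped conv block", call. = FALSE)
  }
  if (any(input_shape[1:2] %% 16 != 0)) {
    stop("input height/width must be divisible by 16", call. = FALSE)
  }
  structure(list(input_shape = as.integer(input_shape),
                 first_conv = as.integer(first_conv),
                 block_repeats = as.integer(block_repeats),
                 channel_schedule = as.integer(channel_schedule),
                 fc_hidden = as.integer(fc_hidden),
                 activation_slope = activation_slope,
                 n_classes = as.integer(n_classes),
                 enforce_budget = isTRUE(enforce_budget)),
            class = "ndcnn_spec")
}

#' N-DCNN training configuration
#'
#' Defaults: SGDM, learning rate 0.001, mini-batch 32, 100 epochs, momentum
#' 0.99, L2 regularization 0.0005, weighted cross-entropy with inverse class
#' frequency weights.
#'
#' @param learning_rate,batch_size,epochs,momentum,l2 training
#'   hyperparameters.
#' @param class_weights optional explicit `(MEL, BEN)` weights; the default
#'   `NULL` uses inverse class frequency of the training labels.
#' @return an object of class `ndcnn_train_config`.
#' @export
ndcnn_train_config <- function(learning_rate = 0.001, batch_size = 32,
                               epochs = 100, momentum = 0.99, l2 = 0.0005,
                               class_weights = NULL) {
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, momentum = momentum, l2 = l2,
                 class_weights = class_weights, optimizer = "SGDM",
                 loss = "weighted cross-entropy"),
            class = "ndcnn_train_config")
}

#' Build the N-DCNN layer description
#'
#' @param spec an [ndcnn_spec()].
#' @return a `network_spec`; errors (naming the offending schedule) when the
#'   spec enforces the parameter budget and the built network falls outside
#'   3.0-3.6 M parameters or 2,800-3,400 kernels.
#' @export
build_ndcnn <- function(spec = ndcnn_spec()) {
  stopifnot(inherits(spec, "ndcnn_spec"))
  s <- spec$activation_slope
  conv_block <- function(cin, cout) {
    list(layer_conv(cin, cout, c(3, 3), 1), layer_batch_norm(cout),
         layer_leaky_relu(s))
  }
  layers <- c(conv_block(spec$input_shape[3], spec$first_conv),
              list(layer_max_pool(2)))
  cin <- spec$first_conv
  k <- 1
  for (g in seq_along(spec$block_repeats)) {
    for (r in seq_len(spec$block_repeats[g])) {
      cout <- spec$channel_schedule[k]
      layers <- c(layers, conv_block(cin, cout))
      cin <- cout
      k <- k + 1
    }
    layers <- c(layers, list(layer_max_pool(2)))
  }
  hw <- spec$input_shape[1:2] %/% 16
  feat <- hw[1] * hw[2] * cin
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(feat, spec$fc_hidden),
    layer_leaky_relu(s),
    layer_dense(spec$fc_hidden, spec$n_classes),
    layer_softmax()))
  net <- new_network_spec(layers, spec$input_shape)
  if (spec$enforce_budget) {
    np <- count_parameters(net)$total
    nk <- count_kernels(net)
    if (np < 3.0e6 || np > 3.6e6 || nk < 2800 || nk > 3400) {
      stop(sprintf(
        "channel schedule [%s] with fc_hidden %d yields %d parameters / %d kernels, outside the 3.0-3.6 M / 2.8-3.4 K budget",
        paste(spec$channel_schedule, collapse = ","), spec$fc_hidden, np, nk),
        call. = FALSE)
    }
  }
  net
}

#' Instantiate an untrained N-DCNN model
#'
#' @param spec an [ndcnn_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `ndcnn_model`.
#' @export
ndcnn_model <- function(spec = ndcnn_spec(), seed = 1L) {
  net <- build_ndcnn(spec)
  ini <- nn_init_params(net, seed)
  structure(list(spec = spec, net = net, params = ini$params,
                 buffers = ini$buffers, classes = c("MEL", "BEN"),
                 trained = FALSE, history = numeric(0)),
            class = "ndcnn_model")
}

ndcnn_prepare_x <- function(model, images) {
  H <- model$spec$input_shape[1]; W <- model$spec$input_shape[2]
  lapply(images, function(im) {
    if (!all(dim(im)[1:2] == c(H, W))) im <- resize_image(im, H, W)
    matrix(im, H * W, 3) / 255
  })
}

#' Train the melanoma/benign classifier
#'
#' Weighted cross-entropy (inverse class frequency by default) minimized by
#' SGDM with the Table-style defaults of [ndcnn_train_config()]. Images are
#' resized to the model input shape and scaled to \[0, 1\]. Deterministic
#' given `seed`; learning rate 0 leaves the weights unchanged.
#'
#' @param model an [ndcnn_model()].
#' @param images list of H x W x 3 arrays.
#' @param labels character vector of `"MEL"`/`"BEN"`, one per image; a
#'   single-class dataset is an error.
#' @param cfg an [ndcnn_train_config()].
#' @param seed integer seed.
#' @return the trained model with `$history` (mean training loss per epoch).
#' @export
train_ndcnn <- function(model, images, labels, cfg = ndcnn_train_config(),
                        seed = 1L) {
  stopifnot(inherits(model, "ndcnn_model"), length(images) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% model$classes)) stop("labels must be MEL or BEN", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("training set contains a single class; both MEL and BEN are required",
         call. = FALSE)
  }
  xs <- ndcnn_prepare_x(model, images)
  T_all <- cbind(as.integer(labels == "MEL"), as.integer(labels == "BEN"))
  w <- cfg$class_weights
  if (is.null(w)) {
    n <- length(labels)
    w <- n / (2 * c(sum(labels == "MEL"), sum(labels == "BEN")))
  }
  HW <- prod(model$spec$input_shape[1:2])
  vel <- sgdm_init_state(model$params)
  history <- numeric(cfg$epochs)
  with_seed(derive_seed(seed, 53), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(xs))
      losses <- numeric(0)
      for (s in seq(1, length(ord), by = cfg$batch_size)) {
        ids <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        B <- length(ids)
        x <- do.call(rbind, xs[ids])
        T_ <- T_all[ids, , drop = FALSE]
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

# batch prediction: returns an N x 2 matrix of (MEL, BEN) probabilities
ndcnn_predict_proba <- function(model, images) {
  xs <- ndcnn_prepare_x(model, images)
  out <- matrix(0, length(images), 2, dimnames = list(NULL, model$classes))
  bs <- 16L
  for (s in seq(1, length(xs), by = bs)) {
    ids <- s:min(s + bs - 1, length(xs))
    x <- do.call(rbind, xs[ids])
    out[ids, ] <- nn_forward(model$net, model$params, model$buffers, x,
                             length(ids), training = FALSE)$out
  }
  out
}

#' Classify a dermoscopic image
#'
#' @param object a trained [ndcnn_model()].
#' @param image H x W x 3 array, 0-255 (resized to the model input).
#' @param ... unused.
#' @return list with `probabilities` (named MEL/BEN, summing to 1) and
#'   `label` (argmax class).
#' @export
predict.ndcnn_model <- function(object, image, ...) {
  assert_rgb_image(image)
  p <- ndcnn_predict_proba(object, list(image))[1, ]
  list(probabilities = p, label = names(p)[which.max(p)])
}
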