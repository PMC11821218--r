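# Shared fixtures and lazily trained tiny models. Heavy artifacts (trained
# networks, evaluation suites) are built once per test run and reused by the
# module and acceptance tests.

.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cache[[name]])) .cache[[name]] <- builder()
  .cache[[name]]
}

# reduced desk-scale configurations (see the methods vignette)
tiny_ndcnn_spec <- function() {
  ndcnn_spec(input_shape = c(64, 64, 3),
             channel_schedule = c(16, 16, 32, 32, 32, 32, 64, 64),
             fc_hidden = 32)
}
tiny_ndcnn_cfg <- function(epochs = 15) {
  ndcnn_train_config(epochs = epochs, batch_size = 16)
}
tiny_acnn_spec <- function() {
  acnn_spec(input_shape = c(48, 64, 3),
            channels_per_block = c(8, 12, 16, 16, 16))
}
tiny_mcan_spec <- function() mcan_spec(patch_size = 32, n_filters = 16)

trained_tiny_mcan <- function() cached("mcan", function() {
  clean <- generate_dataset(6, 6, 0, seed = 100, image_size = c(64, 64))
  train_mcan(mcan_model(tiny_mcan_spec(), seed = 5), clean$clean_images[1:8],
             epochs = 24, learning_rate = 0.02, momentum = 0.9,
             batch_size = 8, seed = 9)
})

trained_tiny_acnn <- function() cached("acnn", function() {
  tr <- generate_dataset(10, 10, 0, seed = 101, image_size = c(48, 64))
  train_acnn(acnn_model(tiny_acnn_spec(), seed = 4), tr$images, tr$masks,
             acnn_train_config(batch_size = 10, epochs = 24,
                               learning_rate = 0.05), seed = 6)
})

# segmentation stage for the two-arm experiment: trained on images that went
# through the same preprocessing front it will see in the pipeline
trained_pipeline_acnn <- function() cached("acnn_pipeline", function() {
  mcan <- trained_tiny_mcan()
  seg_ds <- generate_dataset(10, 10, 0, seed = 101, image_size = c(48, 64),
                             hairy = TRUE, degraded = TRUE)
  seg_imgs <- lapply(seg_ds$images, function(im)
    enhance(mcan, remove_hairlines(im)$image))
  train_acnn(acnn_model(tiny_acnn_spec(), seed = 4), seg_imgs, seg_ds$masks,
             acnn_train_config(batch_size = 10, epochs = 24,
                               learning_rate = 0.05), seed = 6)
})

trained_tiny_ndcnn <- function() cached("ndcnn", function() {
  tr <- generate_dataset(30, 30, 0, seed = 41, image_size = c(64, 64))
  model <- train_ndcnn(ndcnn_model(tiny_ndcnn_spec(), seed = 3),
                       tr$images, tr$index$label, tiny_ndcnn_cfg(), seed = 8)
  list(model = model, train = tr)
})

# direct per-pixel brute-force oracles -------------------------------------

# grayscale dilation/erosion by explicit max/min over the footprint support
brute_morph <- function(gray, fp, op = max) {
  H <- nrow(gray); W <- ncol(gray)
  hr <- (nrow(fp) - 1) / 2; hc <- (ncol(fp) - 1) / 2
  offs <- which(fp != 0, arr.ind = TRUE)
  offs[, 1] <- offs[, 1] - hr - 1
  offs[, 2] <- offs[, 2] - hc - 1
  out <- matrix(0, H, W)
  pad_val <- if (identical(op, max)) -Inf else Inf
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      rr <- r + offs[, 1]; ccs <- cc + offs[, 2]
      ok <- rr >= 1 & rr <= H & ccs >= 1 & ccs <= W
      out[r, cc] <- op(gray[cbind(rr[ok], ccs[ok])])
    }
  }
  out
}

brute_close <- function(gray, fp) {
  # reflected footprint for the erosion step; all package footprints are
  # symmetric, so the plain footprint is used for both passes
  brute_morph(brute_morph(gray, fp, max), fp, min)
}

# triple-loop direct summation of the dilated convolution
brute_atrous <- function(fm, K, rate) {
  if (length(dim(fm)) == 2) fm <- array(fm, dim = c(dim(fm), 1))
  H <- dim(fm)[1]; W <- dim(fm)[2]; C <- dim(fm)[3]
  kh <- dim(K)[1]; kw <- dim(K)[2]; Co <- dim(K)[4]
  hh <- (kh - 1) / 2; hw <- (kw - 1) / 2
  out <- array(0, dim = c(H, W, Co))
  for (o in seq_len(Co)) {
    for (x in seq_len(H)) {
      for (y in seq_len(W)) {
        acc <- 0
        for (i in seq_len(kh)) {
          for (j in seq_len(kw)) {
            sx <- x + (i - hh - 1) * rate
            sy <- y + (j - hw - 1) * rate
            if (sx < 1 || sx > H || sy < 1 || sy > W) next
            for (k in seq_len(C)) acc <- acc + fm[sx, sy, k] * K[i, j, k, o]
          }
        }
        out[x, y, o] <- acc
      }
    }
  }
  out
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
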