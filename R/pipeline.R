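#' Configuration of one experiment arm
#'
#' The two-arm experiment trains and evaluates the same classifier either on
#' raw images (`arm = "raw"`: resize and intensity scaling only) or on
#' preprocessed images (`arm = "preprocessed"`: hairline removal, contrast
#' restoration, segmentation, ROI crop, then the classifier), with identical
#' seeds and hyperparameters in both arms.
#'
#' @param arm `"raw"` or `"preprocessed"`.
#' @param classifier_spec an [ndcnn_spec()] for the classifier.
#' @param train_cfg an [ndcnn_train_config()].
#' @param hair_cfg a [hair_removal_config()] (preprocessed arm).
#' @param mcan_model trained [mcan_model()] (preprocessed arm).
#' @param acnn_model trained [acnn_model()] (preprocessed arm).
#' @param crop_margin ROI margin in pixels.
#' @param seed integer seed shared by both arms.
#' @param out_dir optional directory for predictions/metrics files.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(arm = c("raw", "preprocessed"),
                              classifier_spec, train_cfg,
                              hair_cfg = hair_removal_config(),
                              mcan_model = NULL, acnn_model = NULL,
                              crop_margin = 4, seed = 1L, out_dir = NULL) {
  arm <- match.arg(arm)
  if (arm == "preprocessed") {
    missing_stages <- c(
      if (is.null(mcan_model)) "contrast model (mcan_model)",
      if (is.null(acnn_model)) "segmentation model (acnn_model)")
    if (length(missing_stages) > 0) {
      stop(sprintf("preprocessed arm requires trained stage weights: %s",
                   paste(missing_stages, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(arm = arm, classifier_spec = classifier_spec,
                 train_cfg = train_cfg, hair_cfg = hair_cfg,
                 mcan_model = mcan_model, acnn_model = acnn_model,
                 crop_margin = crop_margin, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

preprocess_one <- function(image, cfg, log_call) {
  log_call("remove_hairlines")
  rh <- remove_hairlines(image, cfg$hair_cfg)
  log_call("enhance")
  en <- enhance(cfg$mcan_model, rh$image)
  log_call("segment")
  mk <- segment(cfg$acnn_model, en)
  if (sum(mk) == 0) {
    # fallback: keep the uncropped image when segmentation finds nothing,
    # rather than failing the whole run
    log_call("crop_fallback")
    return(en)
  }
  log_call("crop_roi")
  crop_roi(en, mk, cfg$crop_margin)
}

#' Run one arm of the two-arm experiment
#'
#' Trains the classifier on the training split and evaluates it on the test
#' split of `index`, preprocessing every image first when
#' `cfg$arm == "preprocessed"`. Deterministic for a fixed configuration and
#' seed. The returned `call_log` records each preprocessing stage invocation
#' (empty in the raw arm).
#'
#' @param cfg an [experiment_config()].
#' @param index dataset index with a `split` column (train/val/test).
#' @param images named list of images keyed by `index$path`.
#' @return list with `report` (a [metric_report()]), `predictions`
#'   (data.frame `path, p_mel, p_ben, label, truth`), `model` (the trained
#'   classifier) and `call_log`.
#' @export
run_arm <- function(cfg, index, images) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!"split" %in% names(index)) {
    stop("index must carry train/val/test split assignments", call. = FALSE)
  }
  calls <- character(0)
  log_call <- function(what) calls[[length(calls) + 1]] <<- what
  prep <- function(img) {
    if (cfg$arm == "preprocessed") preprocess_one(img, cfg, log_call) else img
  }
  prepared <- lapply(index$path, function(p) prep(images[[p]]))
  names(prepared) <- index$path
  tr <- index$split == "train"
  te <- index$split == "test"
  model <- ndcnn_model(cfg$classifier_spec, seed = cfg$seed)
  model <- train_ndcnn(model, prepared[index$path[tr]], index$label[tr],
                       cfg$train_cfg, seed = cfg$seed)
  probs <- ndcnn_predict_proba(model, prepared[index$path[te]])
  pred_lab <- ifelse(probs[, "MEL"] >= probs[, "BEN"], "MEL", "BEN")
  truth <- index$label[te]
  counts <- confusion_from_labels(pred_lab, truth)
  report <- metric_report(counts, scores = probs[, "MEL"],
                          labels = truth == "MEL")
  predictions <- data.frame(path = index$path[te],
                            p_mel = probs[, "MEL"], p_ben = probs[, "BEN"],
                            label = pred_lab, truth = truth,
                            stringsAsFactors = FALSE)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(predictions, file.path(cfg$out_dir,
                                     sprintf("predictions_%s.csv", cfg$arm)),
              row.names = FALSE)
    write.csv(data.frame(metric = c("acc", "pre", "rec", "spe", "f1", "auc"),
                         value = c(report$acc, report$pre, report$rec,
                                   report$spe, report$f1, report$auc)),
              file.path(cfg$out_dir, sprintf("metrics_%s.csv", cfg$arm)),
              row.names = FALSE)
  }
  list(report = report, predictions = predictions, model = model,
       call_log = calls)
}

#' Compare the metric reports of the two arms
#'
#' @param report_raw,report_pre [metric_report()]s computed on the same test
#'   set (mismatched test-set sizes are an error).
#' @return data.frame with one row per metric (acc, pre, rec, spe, f1) and
#'   columns `raw`, `preprocessed`, `delta` (preprocessed minus raw).
#' @export
compare_arms <- function(report_raw, report_pre) {
  stopifnot(inherits(report_raw, "metric_report"),
            inherits(report_pre, "metric_report"))
  n_raw <- report_raw$tp + report_raw$fp + report_raw$tn + report_raw$fn
  n_pre <- report_pre$tp + report_pre$fp + report_pre$tn + report_pre$fn
  if (n_raw != n_pre) {
    stop("the two reports were not computed on the same test set", call. = FALSE)
  }
  metrics <- c("acc", "pre", "rec", "spe", "f1")
  raw <- unlist(report_raw[metrics])
  pre <- unlist(report_pre[metrics])
  data.frame(metric = metrics, raw = raw, preprocessed = pre,
             delta = round_half_up(pre - raw, 2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' Single-file portable checkpoints for any of the package's models.
#'
#' @param model a model object (`mcan_model`, `acnn_model`, `ndcnn_model`).
#' @param path checkpoint file path.
#' @return invisibly `path` (save); the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
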