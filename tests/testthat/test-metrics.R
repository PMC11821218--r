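test_that("the worked confusion matrix reproduces the reference metric row", {
  c_ <- confusion_counts(tp = 1293, fp = 126, tn = 1050, fn = 108)
  expect_identical(accuracy(c_), 90.92)
  expect_identical(precision(c_), 91.12)
  expect_identical(recall(c_), 92.29)
  expect_identical(specificity(c_), 89.29)
  expect_identical(f1_score(c_), 91.70)
})

test_that("metrics agree with label-by-label recounts and algebraic identities", {
  set.seed(5)
  truth <- sample(c("MEL", "BEN"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth, sample(c("MEL", "BEN"), 200, replace = TRUE))
  c_ <- confusion_from_labels(pred, truth)
  # independent tally
  expect_equal(c_$tp, sum(pred == "MEL" & truth == "MEL"))
  expect_equal(c_$tn, sum(pred == "BEN" & truth == "BEN"))
  expect_equal(accuracy(c_), round_half_up(100 * mean(pred == truth), 2))
  # F1 is the harmonic mean of precision and recall (raw fractions)
  pre <- c_$tp / (c_$tp + c_$fp); rec <- c_$tp / (c_$tp + c_$fn)
  expect_equal(f1_score(c_), round_half_up(100 * 2 * pre * rec / (pre + rec), 2))

  perfect <- confusion_counts(5, 0, 5, 0)
  expect_equal(c(accuracy(perfect), precision(perfect), recall(perfect),
                 specificity(perfect), f1_score(perfect)), rep(100, 5))
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "empty")
  expect_warning(p0 <- precision(confusion_counts(0, 0, 5, 5)), "zero denominator")
  expect_equal(p0, 0)
})

test_that("the AUC equals the Mann-Whitney rank statistic and behaves at the extremes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  set.seed(6)
  scores <- round(runif(60), 1)  # coarse scores force ties
  labels <- rbinom(60, 1, 0.4)
  a <- roc_auc(scores, labels)
  # rank-statistic oracle with ties averaged
  r <- rank(scores)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  wilcox <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  expect_equal(a, wilcox, tolerance = 1e-12)
  expect_equal(roc_auc(-scores, labels), 1 - a, tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                   direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("labels independent of scores give an AUC near one half", {
  set.seed(7)
  expect_equal(roc_auc(runif(4000), rbinom(4000, 1, 0.5)), 0.5, tolerance = 0.05)
})

test_that("layer parameter formulas match direct arithmetic and weight enumeration", {
  eng <- asNamespace("dermocad")
  net <- eng$new_network_spec(list(
    eng$layer_conv(3, 8, c(3, 3), 1),   # (3*3*3 + 1) * 8 = 224
    eng$layer_batch_norm(8),            # 2 * 8 = 16
    eng$layer_max_pool(2),              # 0
    eng$layer_leaky_relu(0.3),          # 0
    eng$layer_flatten(),                # 0
    eng$layer_dense(100, 2)), c(8, 8, 3))  # 2*100 + 2 = 202
  cp <- count_parameters(net)
  expect_equal(cp$per_layer, c(224, 16, 0, 0, 0, 202))
  expect_equal(cp$total, 442)
  # brute-force enumeration of instantiated weight arrays
  ini <- eng$nn_init_params(net, 1)
  n_weights <- sum(vapply(ini$params, function(p)
    if (is.null(p)) 0 else sum(vapply(p, length, numeric(1))), numeric(1)))
  expect_equal(n_weights, cp$total)

  bad <- eng$new_network_spec(list(list(kind = "wavelet")), c(8, 8, 1))
  expect_error(count_parameters(bad), "unknown layer kind")
})

test_that("metric reports assemble counts and AUC", {
  r <- metric_report(confusion_counts(8, 2, 7, 3),
                     scores = c(0.9, 0.8, 0.3, 0.2), labels = c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(r$acc, 75)
  expect_output(print(r), "ACC 75.00")
})
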