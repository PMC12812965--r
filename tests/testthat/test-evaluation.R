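test_that("confusion matrices tally true/predicted pairs", {
  # perfect predictions: diagonal
  cm <- compute_confusion(c(1, 2, 3, 1), c(1, 2, 3, 1), 3)
  expect_equal(unname(diag(cm)), c(2, 1, 1))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # constant predictor: one nonzero column
  cmc <- compute_confusion(c(1, 2, 3, 2), rep(2, 4), 3)
  expect_equal(unname(colSums(cmc)), c(0, 4, 0))

  # 10 hand-labeled pairs against a direct tally
  truth <- c(1, 1, 2, 2, 2, 3, 3, 1, 2, 3)
  pred  <- c(1, 2, 2, 2, 1, 3, 1, 1, 2, 3)
  cm10 <- compute_confusion(truth, pred, 3)
  oracle <- matrix(0L, 3, 3)
  for (i in seq_along(truth)) {
    oracle[truth[i], pred[i]] <- oracle[truth[i], pred[i]] + 1L
  }
  expect_equal(unclass(cm10), oracle, ignore_attr = TRUE)

  expect_error(compute_confusion(1:3, 1:2, 3), class = "gliofuse_value_error")
  expect_error(compute_confusion(c(1, 4), c(1, 1), 3),
               class = "gliofuse_value_error")
})

test_that("binary metrics reproduce the contingency formulas", {
  # TP=3, TN=5, FP=1, FN=1 with class 2 as positive
  cm <- matrix(c(5L, 1L, 1L, 3L), 2, 2, byrow = TRUE)
  class(cm) <- c("confusion_matrix", "matrix")
  r <- compute_metrics(cm)
  expect_equal(r$accuracy, (3 + 5) / (3 + 5 + 1 + 1))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$specificity, 5 / 6)
  expect_equal(r$f1, 0.75)
})

test_that("log loss uses natural logs with clamping at exact zeros", {
  cm <- compute_confusion(c(1, 2), c(1, 2), 2)
  # uniform binary probabilities: ln 2
  r <- compute_metrics(cm, probs = matrix(0.5, 2, 2), labels = c(1, 2))
  expect_equal(r$log_loss, log(2))

  # perfect confident probabilities: ~0
  r2 <- compute_metrics(cm, probs = rbind(c(1, 0), c(0, 1)),
                        labels = c(1, 2))
  expect_lte(r2$log_loss, 1e-7)

  # sparse outputs with an exact zero at the true class stay finite
  r3 <- compute_metrics(cm, probs = rbind(c(0, 1), c(0, 1)),
                        labels = c(1, 2))
  expect_equal(r3$log_loss, -log(1e-8) / 2)
  expect_true(is.finite(r3$log_loss))
})

test_that("F1 is the harmonic mean of reported precision and recall", {
  set.seed(51)
  for (i in 1:20) {
    C <- sample(2:4, 1)
    truth <- sample(C, 40, TRUE)
    pred <- sample(C, 40, TRUE)
    r <- compute_metrics(compute_confusion(truth, pred, C))
    pc <- r$per_class
    ok <- !is.na(pc$precision) & !is.na(pc$recall) & pc$precision + pc$recall > 0
    expect_equal(pc$f1[ok],
                 2 * pc$precision[ok] * pc$recall[ok] /
                   (pc$precision[ok] + pc$recall[ok]))
  }
})

test_that("rank-statistic AUC behaves at its extremes and matches pROC", {
  labels <- c(rep(1, 10), rep(2, 10))
  perfect <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  cm <- compute_confusion(labels, labels, 2)
  r <- compute_metrics(cm, probs = cbind(1 - perfect, perfect),
                       labels = labels)
  expect_equal(r$auc, 1)

  inverted <- compute_metrics(cm, probs = cbind(perfect, 1 - perfect),
                              labels = labels)
  expect_equal(inverted$auc, 0)

  set.seed(52)
  rnd_scores <- runif(2000)
  rnd_labels <- sample(1:2, 2000, TRUE)
  rr <- compute_metrics(compute_confusion(rnd_labels, rnd_labels, 2),
                        probs = cbind(1 - rnd_scores, rnd_scores),
                        labels = rnd_labels)
  expect_equal(rr$auc, 0.5, tolerance = 0.05)

  # independent cross-check against pROC on a tied, noisy case
  skip_if_not_installed("pROC")
  set.seed(53)
  sc <- round(runif(60), 1)
  lb <- sample(1:2, 60, TRUE)
  ours <- compute_metrics(compute_confusion(lb, lb, 2),
                          probs = cbind(1 - sc, sc), labels = lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<", levels = c(1, 2))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("metrics are invariant to sample order and flag absent classes", {
  set.seed(54)
  truth <- sample(1:3, 30, TRUE)
  pred <- sample(1:3, 30, TRUE)
  probs <- matrix(runif(90), 30); probs <- probs / rowSums(probs)
  r1 <- compute_metrics(compute_confusion(truth, pred, 3), probs, truth)
  perm <- sample(30)
  r2 <- compute_metrics(compute_confusion(truth[perm], pred[perm], 3),
                        probs[perm, ], truth[perm])
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$f1, r2$f1)
  expect_equal(r1$log_loss, r2$log_loss)
  expect_equal(r1$auc, r2$auc)

  # class 3 absent from the truth: warning, macro mean over the rest
  expect_warning(
    r3 <- compute_metrics(compute_confusion(c(1, 1, 2, 2), c(1, 3, 2, 2), 3)),
    regexp = "absent")
  expect_true(is.na(r3$per_class$recall[3]))
  expect_false(is.na(r3$recall))
})

test_that("reports and ROC curves export to disk", {
  cm <- compute_confusion(c(1, 2, 1, 2), c(1, 2, 2, 2), 2)
  r <- compute_metrics(cm, probs = matrix(0.5, 4, 2), labels = c(1, 2, 1, 2))
  jpath <- tempfile(fileext = ".json")
  write_metrics_json(r, jpath)
  parsed <- jsonlite::fromJSON(jpath)
  expect_equal(parsed$accuracy, r$accuracy)

  cpath <- tempfile(fileext = ".csv")
  write_confusion_csv(cm, cpath)
  expect_equal(unname(as.matrix(read.csv(cpath, row.names = 1))),
               unname(unclass(cm)))

  roc <- roc_points(c(0.9, 0.2, 0.7, 0.4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(roc$tpr[nrow(roc)], 1)
  tpath <- tempfile(fileext = ".tsv")
  write_roc_tsv(roc, tpath)
  expect_equal(nrow(read.delim(tpath)), nrow(roc))
  unlink(c(jpath, cpath, tpath))
})
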