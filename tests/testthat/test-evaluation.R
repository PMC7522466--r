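lv <- task_levels()

test_that("confusion matrix counts agree with hand enumeration", {
  yt <- factor(lv[c(1, 1, 2, 3, 4, 4, 2, 1, 3, 3, 4, 2)], levels = lv)
  yp <- factor(lv[c(1, 2, 2, 3, 4, 1, 2, 1, 3, 4, 4, 2)], levels = lv)
  cm <- confusion(yt, yp)
  hand <- matrix(0L, 4, 4)
  for (i in seq_along(yt)) {
    hand[as.integer(yt)[i], as.integer(yp)[i]] <-
      hand[as.integer(yt)[i], as.integer(yp)[i]] + 1L
  }
  expect_equal(unname(unclass(cm)), hand, ignore_attr = TRUE)
  expect_equal(sum(cm), 12)

  perfect <- confusion(yt, yt)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  all1 <- confusion(yt, factor(rep(lv[1], 12), levels = lv))
  expect_true(all(all1[, -1] == 0))
})

test_that("global accuracy is trace over total and permutation-invariant", {
  cm <- matrix(c(9, 1, 2, 0,
                 1, 8, 1, 0,
                 0, 2, 7, 1,
                 1, 0, 1, 6), 4, 4, byrow = TRUE)
  expect_equal(global_accuracy(cm), (9 + 8 + 7 + 6) / 40)   # 0.75
  expect_equal(global_accuracy(diag(c(3, 5, 2, 1))), 1.0)
  off <- matrix(1, 4, 4) - diag(4)
  expect_equal(global_accuracy(off), 0.0)
  pm <- sample(4)
  expect_equal(global_accuracy(cm[pm, pm]), global_accuracy(cm))
})

test_that("precision, recall and F-score follow their definitions, with the zero-denominator rule", {
  # class 1: TP=9, FP=1, FN=3
  cm <- matrix(0, 4, 4)
  cm[1, 1] <- 9; cm[2, 1] <- 1; cm[1, 2] <- 3
  cm[2, 2] <- 5; cm[3, 3] <- 2; cm[4, 4] <- 1
  prf <- suppressWarnings(precision_recall_fscore(cm))
  expect_equal(prf$precision[1], 0.9)
  expect_equal(prf$recall[1], 0.75)
  expect_equal(prf$fscore[1], 2 * 0.9 * 0.75 / 1.65)
  expect_equal(unlist(prf[3, c("precision", "recall", "fscore")]),
               c(precision = 1, recall = 1, fscore = 1))
  # a class neither predicted nor present reports 0s with a warning
  cm0 <- diag(c(2, 3, 4, 0))
  w <- capture_warnings(prf0 <- precision_recall_fscore(cm0))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(unlist(prf0[4, c("precision", "recall", "fscore")]),
               c(precision = 0, recall = 0, fscore = 0))
  # one-vs-rest TP over classes sums to the trace
  expect_equal(sum(diag(cm)), sum(prf$recall * rowSums(cm)))
})

test_that("ROC sweep equals exhaustive Mann-Whitney pair counting, including ties", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    truth <- rbinom(n, 1, 0.5)
    if (all(truth == 1) || all(truth == 0)) next
    scores <- round(runif(n), sample(c(1, 2, 8), 1))   # coarse => ties
    r <- paircnn:::roc_sweep(scores, truth)
    expect_equal(r$auc, oracle_auc(scores, truth), tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 and label-free scores give 0.5", {
  r <- paircnn:::roc_sweep(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  set.seed(5)
  n <- 10000
  scores <- matrix(runif(n * 4), n, 4)
  y <- sample(1:4, n, TRUE)
  micro <- roc_auc(scores, y, mode = "micro")
  expect_lt(abs(micro$auc - 0.5), 0.02)
})

test_that("per-class and micro ROC modes are consistent on a small case", {
  set.seed(3)
  probs <- matrix(runif(40), 10, 4)
  probs <- probs / rowSums(probs)
  y <- factor(lv[sample(1:4, 10, TRUE)], levels = lv)
  per <- roc_auc(probs, y, mode = "per_class_ovr")
  expect_length(per, 4)
  onehot <- outer(as.integer(y), 1:4, "==") * 1
  for (k in 1:4) {
    expect_equal(per[[k]]$auc, oracle_auc(probs[, k], onehot[, k]))
  }
  micro <- roc_auc(probs, y, mode = "micro")
  expect_equal(micro$auc, oracle_auc(as.vector(probs), as.vector(onehot)))
})

test_that("metrics_report bundles all quantities coherently", {
  set.seed(12)
  y <- factor(lv[sample(1:4, 60, TRUE)], levels = lv)
  probs <- matrix(runif(240), 60, 4)
  # make predictions informative for most rows
  probs[cbind(1:60, as.integer(y))] <- probs[cbind(1:60, as.integer(y))] + 1.5
  probs <- probs / rowSums(probs)
  colnames(probs) <- lv
  rep <- metrics_report(y, probs)
  expect_equal(rep$n_samples, 60)
  expect_equal(rep$global_accuracy, global_accuracy(rep$confusion))
  expect_true(all(tidy(rep)$precision >= 0 & tidy(rep)$precision <= 1))
  expect_named(rep$auc, c(lv, "pooled"))
  expect_equal(glance(rep)$auc, rep$roc$micro$auc)
})

test_that("report aggregation averages rates and sums counts", {
  set.seed(2)
  mk <- function(acc_shift) {
    y <- factor(lv[sample(1:4, 40, TRUE)], levels = lv)
    probs <- matrix(runif(160), 40, 4)
    probs[cbind(1:40, as.integer(y))] <- probs[cbind(1:40, as.integer(y))] +
      acc_shift
    probs <- probs / rowSums(probs)
    colnames(probs) <- lv
    metrics_report(y, probs)
  }
  r1 <- mk(2); r2 <- mk(0.3)
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$global_accuracy,
               mean(c(r1$global_accuracy, r2$global_accuracy)))
  expect_equal(agg$n_samples, 80)
  expect_equal(aggregate_reports(list(r1, r1))$global_accuracy,
               r1$global_accuracy)
  # nine identical-shape reports: mean equals the hand average
  reps <- lapply(1:9, function(i) mk(runif(1, 0.2, 2)))
  agg9 <- aggregate_reports(reps)
  expect_equal(agg9$global_accuracy,
               mean(vapply(reps, `[[`, numeric(1), "global_accuracy")))
  # weighted variant reduces to the same thing for equal n
  expect_equal(aggregate_reports(reps, weights = "by_n")$global_accuracy,
               agg9$global_accuracy)
})
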