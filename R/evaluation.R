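#' Multiclass confusion matrix
#'
#' @param y_true,y_pred Factors or vectors coercible to factors on the same
#'   level set; rows are the true class, columns the predicted class.
#' @param levels Class levels; defaults to the union of levels in the inputs.
#' @return Integer matrix of class `paircnn_confusion`.
#' @export
confusion <- function(y_true, y_pred, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (is.factor(y_true)) levels(y_true) else
      sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  yt <- factor(y_true, levels = levels)
  yp <- factor(y_pred, levels = levels)
  stopifnot(length(yt) == length(yp), !anyNA(yt), !anyNA(yp))
  cm <- unclass(table(true = yt, predicted = yp))
  class(cm) <- c("paircnn_confusion", "matrix")
  cm
}

#' Global accuracy from a confusion matrix
#'
#' The ratio of correctly classified samples to all samples — for a
#' multiclass matrix, the trace over the grand total.  (The textbook binary
#' form `(TP+TN)/(TP+TN+FP+FN)` reduces to exactly this quantity when "TP+TN"
#' is read as "all correct decisions".)
#'
#' @param cm Confusion matrix from [confusion()].
#' @return Accuracy in `[0, 1]`.
#' @export
global_accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

#' One-vs-rest precision, recall and F-score per class
#'
#' For each class: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F = 2PR/(P+R)`.  A zero denominator yields 0 with a warning (the class
#' was never predicted, never present, or both).
#'
#' @param cm Confusion matrix from [confusion()].
#' @param task Optional single class (name or index) to report.
#' @return Tibble with columns `task`, `precision`, `recall`, `fscore`, and
#'   `accuracy` (per-class recall, the diagonal rate commonly reported as
#'   "task accuracy").
#' @export
precision_recall_fscore <- function(cm, task = NULL) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) warning("zero denominator in ", what, "; reporting 0",
                          call. = FALSE)
    ifelse(bad, 0, num / den)
  }
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f <- safe_div(2 * p * r, p + r, "F-score")
  out <- tibble::tibble(task = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                        precision = p, recall = r, fscore = f, accuracy = r)
  if (!is.null(task)) out <- out[out$task == task | seq_len(nrow(out)) == task, ]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Binary ROC sweep: scores for the positive class vs 0/1 truth.
# Ties are grouped at one threshold; AUC is the trapezoidal area, which
# equals the Mann-Whitney pair-counting statistic with ties counted 1/2.
roc_sweep <- function(scores, truth) {
  if (sum(truth) == 0 || sum(1 - truth) == 0) {
    return(list(points = tibble::tibble(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)      # last index of each tie group
  tpr <- c(0, cum_tp[keep]) / max(sum(y), 1)
  fpr <- c(0, cum_fp[keep]) / max(sum(1 - y), 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = tibble::tibble(fpr = fpr, tpr = tpr), auc = auc)
}

#' One-vs-rest ROC curves and AUC
#'
#' Sweeps a threshold over the unique scores.  `"per_class_ovr"` returns one
#' curve per class; `"micro"` pools every (sample, class) pair into a single
#' binary problem — the reduction used for a single headline AUC.
#'
#' @param scores `n x k` matrix of class scores/probabilities.
#' @param y_true Factor or integer true classes (levels matching columns).
#' @param mode `"micro"` or `"per_class_ovr"`.
#' @return For `"micro"`: list with `points` (tibble `fpr`, `tpr`) and `auc`.
#'   For `"per_class_ovr"`: named list of those, one per class.
#' @export
roc_auc <- function(scores, y_true, mode = c("micro", "per_class_ovr")) {
  mode <- match.arg(mode)
  scores <- as.matrix(scores)
  yt <- if (is.factor(y_true)) as.integer(y_true) else as.integer(y_true)
  stopifnot(length(yt) == nrow(scores), all(yt >= 1), all(yt <= ncol(scores)))
  onehot <- matrix(0, nrow(scores), ncol(scores))
  onehot[cbind(seq_along(yt), yt)] <- 1
  if (mode == "micro") {
    roc_sweep(as.vector(scores), as.vector(onehot))
  } else {
    out <- lapply(seq_len(ncol(scores)), function(k) {
      roc_sweep(scores[, k], onehot[, k])
    })
    names(out) <- colnames(scores) %||% paste0("class_", seq_len(ncol(scores)))
    out
  }
}

#' Full metric report for one evaluated set
#'
#' Bundles the confusion matrix, global and per-task accuracy, one-vs-rest
#' precision/recall/F-score, per-class ROC curves with AUC, and the pooled
#' (micro-averaged) AUC.
#'
#' @param y_true True task labels (factor).
#' @param probs `n x k` matrix of predicted class probabilities; column names
#'   should carry the task levels.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(y_true, probs) {
  lev <- if (is.factor(y_true)) levels(y_true) else colnames(probs)
  pred <- factor(lev[max.col(as.matrix(probs), ties.method = "first")],
                 levels = lev)
  cm <- confusion(y_true, pred, levels = lev)
  prf <- suppressWarnings(precision_recall_fscore(cm))
  per_class <- roc_auc(probs, y_true, mode = "per_class_ovr")
  micro <- roc_auc(probs, y_true, mode = "micro")
  structure(list(
    confusion = cm,
    global_accuracy = global_accuracy(cm),
    per_task = prf,
    roc = list(per_class = per_class, micro = micro),
    auc = c(stats::setNames(vapply(per_class, `[[`, numeric(1), "auc"),
                            names(per_class)), pooled = micro$auc),
    n_samples = length(y_true),
    provenance = list()),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", x$n_samples, "samples; accuracy",
      signif(x$global_accuracy, 4), "; pooled AUC",
      signif(x$auc[["pooled"]], 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Average several metric reports
#'
#' Arithmetic mean of all rates — uniform by default, matching the convention
#' of averaging over cross-validation repeats or electrode pairs — or
#' weighted by each report's sample count.  Confusion matrices and sample
#' counts are summed.
#'
#' @param reports List of [metrics_report()] objects.
#' @param weights `"uniform"` or `"by_n"`.
#' @return A `metrics_report` whose rate fields are the (weighted) means.
#'   ROC point sets are not averaged and are dropped.
#' @export
aggregate_reports <- function(reports, weights = c("uniform", "by_n")) {
  weights <- match.arg(weights)
  stopifnot(length(reports) >= 1L)
  w <- if (weights == "uniform") rep(1, length(reports)) else
    vapply(reports, `[[`, numeric(1), "n_samples")
  w <- w / sum(w)
  wmean <- function(f) {
    Reduce(`+`, Map(function(r, wi) wi * f(r), reports, w))
  }
  cm <- Reduce(`+`, lapply(reports, `[[`, "confusion"))
  class(cm) <- c("paircnn_confusion", "matrix")
  per_task <- reports[[1]]$per_task
  for (cc in c("precision", "recall", "fscore", "accuracy")) {
    per_task[[cc]] <- wmean(function(r) r$per_task[[cc]])
  }
  structure(list(
    confusion = cm,
    global_accuracy = wmean(function(r) r$global_accuracy),
    per_task = per_task,
    roc = NULL,
    auc = wmean(function(r) r$auc),
    n_samples = sum(vapply(reports, `[[`, numeric(1), "n_samples")),
    provenance = list(aggregated_from = length(reports), weights = weights)),
    class = "metrics_report")
}
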