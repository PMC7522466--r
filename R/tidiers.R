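#' Tidy a metric report into a per-task tibble
#'
#' @param x A [metrics_report()].
#' @param ... Unused.
#' @return Tibble with one row per task: precision, recall, F-score,
#'   per-task accuracy and one-vs-rest AUC.
#' @export
tidy.metrics_report <- function(x, ...) {
  out <- x$per_task
  if (!is.null(x$roc)) {
    out$auc <- vapply(x$roc$per_class, `[[`, numeric(1), "auc")
  }
  out
}

#' One-row summary of a metric report
#'
#' @param x A [metrics_report()].
#' @param ... Unused.
#' @return Tibble with `global_accuracy`, `auc` (pooled one-vs-rest),
#'   `n_samples`.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(global_accuracy = x$global_accuracy,
                 auc = x$auc[["pooled"]],
                 n_samples = x$n_samples)
}

#' Tidy a fit's training history
#'
#' @param x A `paircnn_fit` from [train_network()].
#' @param ... Unused.
#' @return The history tibble (iteration, train_loss, and checkpointed
#'   test_loss / test_accuracy when a held-out set was tracked).
#' @export
tidy.paircnn_fit <- function(x, ...) x$history

#' One-row summary of a trained fit
#'
#' @param x A `paircnn_fit`.
#' @param ... Unused.
#' @return Tibble with iterations, final (100-iteration mean) training loss,
#'   last held-out accuracy if tracked, and the parameter count.
#' @export
glance.paircnn_fit <- function(x, ...) {
  h <- x$history
  last_acc <- if ("test_accuracy" %in% names(h)) {
    utils::tail(stats::na.omit(h$test_accuracy), 1)
  } else NA_real_
  tibble::tibble(
    iterations = nrow(h),
    final_train_loss = mean(utils::tail(h$train_loss, 100L)),
    test_accuracy = if (length(last_acc)) last_acc else NA_real_,
    n_parameters = count_parameters(x$config))
}

#' Per-fold accuracies of a cross-validation run
#'
#' @param x A `paircnn_cv` from [run_cross_validation()].
#' @param ... Unused.
#' @return Tibble with one row per fold: fold, global_accuracy, auc,
#'   n_samples.
#' @export
tidy.paircnn_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$reports), function(f) {
    dplyr::bind_cols(tibble::tibble(fold = as.integer(f)),
                     glance(x$reports[[f]]))
  }))
}

#' One-row summary of a cross-validation run
#'
#' @param x A `paircnn_cv`.
#' @param ... Unused.
#' @return Tibble with the number of folds, mean and sd of the fold
#'   accuracies, mean pooled AUC, and total evaluated samples.
#' @export
glance.paircnn_cv <- function(x, ...) {
  per <- tidy(x)
  tibble::tibble(n_folds = nrow(per),
                 mean_accuracy = mean(per$global_accuracy),
                 sd_accuracy = stats::sd(per$global_accuracy),
                 mean_auc = mean(per$auc),
                 n_samples = sum(per$n_samples))
}

#' Plot training and held-out loss curves
#'
#' @param object A `paircnn_fit`.
#' @param smooth Window (iterations) for the running-mean smoothing of the
#'   training loss.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paircnn_fit <- function(object, smooth = 25L, ...) {
  h <- object$history
  smooth <- max(1L, min(as.integer(smooth), nrow(h)))
  h$smoothed <- stats::filter(h$train_loss, rep(1 / smooth, smooth),
                              sides = 1)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$train_loss),
                       alpha = 0.25, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed, colour = "training"),
                       na.rm = TRUE) +
    ggplot2::labs(x = "iteration", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
  if ("test_loss" %in% names(h)) {
    ck <- h[!is.na(h$test_loss), , drop = FALSE]
    p <- p + ggplot2::geom_line(data = ck,
                                ggplot2::aes(y = .data$test_loss,
                                             colour = "held-out"))
  }
  p
}

#' Plot one-vs-rest ROC curves of a metric report
#'
#' @param object A [metrics_report()].
#' @param ... Unused.
#' @return A ggplot object with one curve per task (AUC in the legend) plus
#'   the pooled micro-average.
#' @export
autoplot.metrics_report <- function(object, ...) {
  if (is.null(object$roc)) stop("report carries no ROC curves", call. = FALSE)
  curves <- c(object$roc$per_class, list(pooled = object$roc$micro))
  df <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    pts <- curves[[nm]]$points
    pts$curve <- sprintf("%s (AUC %.3f)", nm, curves[[nm]]$auc)
    pts
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation accuracies
#'
#' @param object A `paircnn_cv`.
#' @param ... Unused.
#' @return A ggplot column chart of fold accuracies with the mean marked.
#' @export
autoplot.paircnn_cv <- function(object, ...) {
  per <- tidy(object)
  ggplot2::ggplot(per, ggplot2::aes(x = factor(.data$fold),
                                    y = .data$global_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(per$global_accuracy),
                        linetype = 2) +
    ggplot2::labs(x = "fold", y = "held-out accuracy") +
    ggplot2::theme_minimal()
}
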