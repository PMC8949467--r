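#' Classification evaluation
#'
#' Confusion counts, the eight-metric report (SEN, SPE, FPR, FNR, PPV, NPV,
#' ACC, F1) and ROC/AUC used both inside cross-validated tuning and for
#' final test-set model selection.
#'
#' @name evaluation
NULL

#' Two-class confusion counts
#'
#' @param truth Character/factor vector of true class labels.
#' @param prediction Predicted class labels, same length and vocabulary.
#' @param positive Name of the positive class.
#' @return An `rrf_confusion` list with fields `tp`, `fp`, `tn`, `fn`,
#'   `positive`, `negative`.
#' @export
confusion_counts <- function(truth, prediction, positive) {
  truth <- as.character(truth); prediction <- as.character(prediction)
  if (length(truth) != length(prediction)) {
    abort("truth and prediction must have the same length.")
  }
  classes <- unique(c(truth, prediction))
  if (!positive %in% classes) {
    abort(sprintf("Positive class '%s' absent from labels/predictions.", positive))
  }
  if (length(classes) > 2L) {
    abort(paste0("Expected a two-class problem; saw classes: ",
                 paste(classes, collapse = ", ")))
  }
  negative <- setdiff(classes, positive)
  if (length(negative) == 0L) negative <- paste0("not_", positive)
  structure(list(
    tp = sum(truth == positive & prediction == positive),
    fp = sum(truth != positive & prediction == positive),
    tn = sum(truth != positive & prediction != positive),
    fn = sum(truth == positive & prediction != positive),
    positive = positive, negative = negative[1]
  ), class = "rrf_confusion")
}

#' @export
print.rrf_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c(x$positive, x$negative),
                              predicted = c(x$positive, x$negative)))
  print(m)
  invisible(x)
}

#' The eight-metric classification report
#'
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `FPR = FP/(FP+TN)`,
#' `FNR = FN/(FN+TP)`, `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`,
#' `ACC = (TP+TN)/N`, `F1 = 2TP/(2TP+FP+FN)`. A ratio with a zero
#' denominator is reported as 0 and its name recorded in the `degenerate`
#' attribute, so batch evaluation over many folds never aborts.
#'
#' @param cm An `rrf_confusion` from [confusion_counts()].
#' @return A one-row tibble with columns `sen`, `spe`, `fpr`, `fnr`, `ppv`,
#'   `npv`, `acc`, `f1` and attribute `degenerate` (character vector of
#'   zero-denominator metrics).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "rrf_confusion"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0L) abort("Empty confusion matrix.")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- tibble(
    sen = ratio(cm$tp, cm$tp + cm$fn),
    spe = ratio(cm$tn, cm$tn + cm$fp),
    fpr = ratio(cm$fp, cm$fp + cm$tn),
    fnr = ratio(cm$fn, cm$fn + cm$tp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    acc = (cm$tp + cm$tn) / n,
    f1 = ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  )
  degen <- names(out)[vapply(out, is.na, logical(1))]
  out[degen] <- 0
  attr(out, "degenerate") <- degen
  out
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct scores (plus sentinels at
#' the two ends) and integrates the curve by the trapezoidal rule; this
#' equals the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counted 1/2.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels True class labels.
#' @param positive Name of the positive class.
#' @return An `rrf_roc` object: a tibble of `(threshold, fpr, tpr)` points
#'   ordered by FPR, with attributes `auc`, `positive`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  y <- labels == positive
  if (all(y) || !any(y)) {
    abort("ROC requires both classes to be present.")
  }
  # classify score >= threshold as positive; +Inf sentinel yields (0, 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  pts <- tibble(threshold = thr, fpr = fpr, tpr = tpr) |>
    dplyr::arrange(.data$fpr, .data$tpr) |>
    dplyr::distinct(.data$fpr, .data$tpr, .keep_all = TRUE)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(pts, class = c("rrf_roc", class(pts)),
            auc = auc, positive = positive,
            n_pos = sum(y), n_neg = sum(!y))
}

#' @export
print.rrf_roc <- function(x, ...) {
  cat(sprintf("<rrf_roc> positive = '%s', %d+/%d- observations, AUC = %.4f\n",
              attr(x, "positive"), attr(x, "n_pos"), attr(x, "n_neg"),
              attr(x, "auc")))
  NextMethod()
}

#' Area under an ROC curve
#'
#' @param roc An `rrf_roc` from [roc_curve()].
#' @return The AUC as a single number.
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "rrf_roc"))
  attr(roc, "auc")
}

#' @rdname roc_curve
#' @param object,x An `rrf_roc` object.
#' @param ... Unused.
#' @export
autoplot.rrf_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (positive = %s), AUC = %.3f",
                      attr(object, "positive"), attr(object, "auc"))) +
    ggplot2::theme_minimal()
}
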