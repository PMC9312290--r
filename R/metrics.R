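# Multi-label evaluation metrics.
#
# Hamming loss (fraction of misclassified label positions), Jaccard
# similarity (per-instance intersection over union, averaged), accuracy in
# two documented readings — bitwise (TP+TN over all n*m positions, the
# complement of Hamming loss) and subset (exact-match rate) — and
# micro/macro precision, recall and F1, plus per-label confusion tables.

.check_pred <- function(Y_true, Y_pred) {
  Y_true <- as.matrix(Y_true); Y_pred <- as.matrix(Y_pred)
  if (!all(dim(Y_true) == dim(Y_pred))) {
    stopf("Y_true and Y_pred must have identical shape")
  }
  if (!all(Y_true %in% c(0, 1)) || !all(Y_pred %in% c(0, 1))) {
    stopf("label matrices must be binary")
  }
  list(Y = Y_true, P = Y_pred)
}

#' Hamming loss
#'
#' Mean over all instances and labels of the disagreement indicator.
#'
#' @param Y_true,Y_pred n x m binary matrices.
#' @return Scalar in `[0, 1]`.
#' @export
hamming_loss <- function(Y_true, Y_pred) {
  z <- .check_pred(Y_true, Y_pred)
  mean(z$Y != z$P)
}

#' Jaccard similarity
#'
#' Mean over instances of |predicted intersect true| / |predicted union
#' true| of the label sets. An instance with an empty union (no true and no
#' predicted labels) scores 1 by convention, since prediction and truth
#' agree exactly there.
#'
#' @param Y_true,Y_pred n x m binary matrices.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_similarity <- function(Y_true, Y_pred) {
  z <- .check_pred(Y_true, Y_pred)
  inter <- rowSums(z$Y == 1 & z$P == 1)
  uni <- rowSums(z$Y == 1 | z$P == 1)
  mean(ifelse(uni == 0, 1, inter / uni))
}

#' Multi-label accuracy
#'
#' `mode = "bitwise"` (default): (TP + TN) / (TP + FN + FP + TN) over all
#' n x m label positions — the complement of Hamming loss. `mode =
#' "subset"`: fraction of instances whose entire predicted label set matches
#' the truth. Both readings are exposed because the bitwise ratio is
#' ambiguous for multi-label data; reports should state the mode.
#'
#' @param Y_true,Y_pred n x m binary matrices.
#' @param mode `"bitwise"` or `"subset"`.
#' @return Scalar in `[0, 1]`.
#' @export
ml_accuracy <- function(Y_true, Y_pred, mode = c("bitwise", "subset")) {
  mode <- match.arg(mode)
  z <- .check_pred(Y_true, Y_pred)
  if (mode == "bitwise") mean(z$Y == z$P) else mean(rowSums(z$Y != z$P) == 0)
}

#' Precision, recall and F1
#'
#' Micro averaging (default) pools true/false positives over all labels;
#' macro averaging computes per-label scores and averages them. F1 is the
#' harmonic mean `2PR/(P+R)`, defined as 0 when `P + R = 0` (and per-label
#' scores with no positive truth and no positive prediction count as 0
#' under macro averaging).
#'
#' @param Y_true,Y_pred n x m binary matrices.
#' @param averaging `"micro"` or `"macro"`.
#' @return Tibble with columns `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(Y_true, Y_pred,
                                averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  z <- .check_pred(Y_true, Y_pred)
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  if (averaging == "micro") {
    tp <- sum(z$Y == 1 & z$P == 1)
    fp <- sum(z$Y == 0 & z$P == 1)
    fn <- sum(z$Y == 1 & z$P == 0)
    v <- prf(tp, fp, fn)
  } else {
    per <- vapply(seq_len(ncol(z$Y)), function(j) {
      prf(sum(z$Y[, j] == 1 & z$P[, j] == 1),
          sum(z$Y[, j] == 0 & z$P[, j] == 1),
          sum(z$Y[, j] == 1 & z$P[, j] == 0))
    }, numeric(3))
    v <- rowMeans(per)
  }
  tibble::tibble(precision = v[1], recall = v[2], f1 = v[3])
}

#' Per-label confusion tables
#'
#' For each label, the 2 x 2 cross-tabulation of instances belonging /
#' not belonging to the label against predictions.
#'
#' @param Y_true,Y_pred n x m binary matrices.
#' @return Tibble with one row per label: `label`, `tp`, `fp`, `fn`, `tn`.
#' @export
per_label_confusion <- function(Y_true, Y_pred) {
  z <- .check_pred(Y_true, Y_pred)
  labels <- colnames(z$Y) %||% paste0("label_", seq_len(ncol(z$Y)))
  purrr::map_dfr(seq_len(ncol(z$Y)), function(j) {
    tibble::tibble(
      label = labels[j],
      tp = sum(z$Y[, j] == 1 & z$P[, j] == 1),
      fp = sum(z$Y[, j] == 0 & z$P[, j] == 1),
      fn = sum(z$Y[, j] == 1 & z$P[, j] == 0),
      tn = sum(z$Y[, j] == 0 & z$P[, j] == 0)
    )
  })
}

#' Full multi-label evaluation report
#'
#' Computes all metrics in one pass: bitwise and subset accuracy, Hamming
#' loss, Jaccard similarity and micro/macro precision/recall/F1.
#'
#' @param Y_true,Y_pred n x m binary matrices.
#' @return A `metric_report`: one-row tibble of metrics, with the per-label
#'   confusion tibble in attribute `"confusion"`.
#' @examples
#' Y <- matrix(rbinom(30, 1, 0.4), 10, 3)
#' evaluate_multilabel(Y, Y)$hamming_loss
#' @export
evaluate_multilabel <- function(Y_true, Y_pred) {
  micro <- precision_recall_f1(Y_true, Y_pred, "micro")
  macro <- precision_recall_f1(Y_true, Y_pred, "macro")
  out <- tibble::tibble(
    accuracy = ml_accuracy(Y_true, Y_pred, "bitwise"),
    subset_accuracy = ml_accuracy(Y_true, Y_pred, "subset"),
    hamming_loss = hamming_loss(Y_true, Y_pred),
    jaccard = jaccard_similarity(Y_true, Y_pred),
    precision = micro$precision, recall = micro$recall, f1 = micro$f1,
    macro_precision = macro$precision, macro_recall = macro$recall,
    macro_f1 = macro$f1
  )
  attr(out, "confusion") <- per_label_confusion(Y_true, Y_pred)
  attr(out, "accuracy_mode") <- "bitwise (subset reported separately)"
  class(out) <- c("metric_report", class(out))
  out
}

#' Per-label ROC points over a threshold sweep
#'
#' @param Y_true n x m binary matrix.
#' @param P n x m probability matrix.
#' @param thresholds Cut-offs to sweep (default 101 points in `[0, 1]`).
#' @return Tibble: `label`, `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(Y_true, P, thresholds = seq(0, 1, by = 0.01)) {
  Y_true <- as.matrix(Y_true)
  labels <- colnames(Y_true) %||% paste0("label_", seq_len(ncol(Y_true)))
  purrr::map_dfr(seq_len(ncol(Y_true)), function(j) {
    purrr::map_dfr(thresholds, function(th) {
      pred <- P[, j] >= th
      pos <- Y_true[, j] == 1
      tibble::tibble(
        label = labels[j], threshold = th,
        tpr = if (any(pos)) sum(pred & pos) / sum(pos) else NA_real_,
        fpr = if (any(!pos)) sum(pred & !pos) / sum(!pos) else NA_real_
      )
    })
  })
}

#' Plot per-label confusion counts
#'
#' @param report A `metric_report` (or any tibble with a `"confusion"`
#'   attribute).
#' @return A ggplot object.
#' @export
plot_confusion <- function(report) {
  conf <- attr(report, "confusion")
  df <- tidyr::pivot_longer(conf, c("tp", "fp", "fn", "tn"),
                            names_to = "cell", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(title = "Per-label confusion counts", x = NULL) +
    ggplot2::theme_minimal()
}
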