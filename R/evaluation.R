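# Confusion-matrix construction and support-weighted metrics.

#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted vectors of class labels (coerced to the union of
#'   `labels`); `labels` optional explicit label ordering.
#' @return A `confusion_matrix`: integer C x C table, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  labels <- labels %||% sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = labels),
              factor(predicted, levels = labels))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("truth", "predicted")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Support-weighted multiclass metrics
#'
#' Per class `c`: `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F = 2 P R / (P + R)`; each weighted metric is
#' `sum_c (support_c / N) * metric_c` and accuracy is `trace / N`.
#' Support-weighted recall is algebraically identical to overall accuracy,
#' which is also how the "weighted accuracy" panel is reported.  Per-class
#' metrics with a zero denominator are set to 0 and flagged.
#'
#' @param cm a [confusion_matrix()] (or plain square count matrix).
#' @return An `eval_report` list: `per_class` data frame (`label`,
#'   `precision`, `recall`, `f_measure`, `support`, `zero_division`),
#'   `weighted` named vector (`accuracy`, `precision`, `recall`,
#'   `f_measure`), and `confusion`.
#' @export
weighted_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, pred_tot)
  recall <- safe_div(tp, support)
  f <- safe_div(2 * precision * recall, precision + recall)
  wt <- support / n
  per_class <- data.frame(
    label = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    precision = precision, recall = recall, f_measure = f,
    support = support,
    zero_division = pred_tot == 0 | support == 0 |
      (precision + recall) == 0,
    row.names = NULL)
  weighted <- c(accuracy = sum(tp) / n,
                precision = sum(wt * precision),
                recall = sum(wt * recall),
                f_measure = sum(wt * f))
  structure(list(per_class = per_class, weighted = weighted,
                 confusion = structure(cm, class = c("confusion_matrix",
                                                     class(cm)))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Weighted metrics:\n")
  print(round(x$weighted, 4))
  cat("\nPer-class:\n")
  print(cbind(x$per_class[, 1, drop = FALSE],
              round(x$per_class[, 2:4], 4),
              x$per_class[, 5, drop = FALSE]), row.names = FALSE)
  invisible(x)
}

#' Evaluate a trained network on one split of a manifest
#'
#' Runs inference (dropout off) over every crop of the chosen split and
#' summarizes the result as a confusion matrix plus support-weighted
#' accuracy, precision, recall and F-measure.
#'
#' @param net a trained `diatomnet_network`.
#' @param crops crop list covering the manifest.
#' @param manifest a `dataset_manifest`.
#' @param split `"train"`, `"validation"` or `"test"`.
#' @param batch_size inference batch size.
#' @return An `eval_report` (see [weighted_metrics()]).
#' @export
evaluate_network <- function(net, crops, manifest, split = "test",
                             batch_size = 32L) {
  if (!split %in% c("train", "validation", "test"))
    stop("unknown split: ", split)
  labels <- attr(net, "labels") %||% sort(unique(manifest$species))
  if (length(labels) != net$spec$num_classes)
    stop("label set size (", length(labels),
         ") does not match network classes (", net$spec$num_classes, ")")
  sel <- crops_by_split(crops, manifest, split)
  if (length(sel) == 0) stop("empty split: ", split)
  truth <- vapply(sel, `[[`, "", "species")
  if (!all(truth %in% labels))
    stop("species in manifest absent from the network's label set")
  xs <- lapply(sel, `[[`, "pixels")
  pred <- character(length(sel))
  for (start in seq(1, length(sel), by = batch_size)) {
    ids <- start:min(start + batch_size - 1, length(sel))
    fw <- forward_batch(net, bind_batch(xs[ids]))
    pred[ids] <- labels[apply(fw$probs, 2, which.max)]
  }
  weighted_metrics(confusion_matrix(truth, pred, labels))
}

#' Serialize an evaluation report as structured text
#' @param report an `eval_report`; `path` output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(weighted = as.list(report$weighted),
         per_class = report$per_class,
         confusion = list(labels = rownames(report$confusion),
                          counts = unclass(report$confusion))),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
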