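#' Binary confusion matrix from prediction/truth pairs
#'
#' Tallies a 2x2 confusion matrix with the spray category as the positive
#' class: `tp` (predicted and true positive), `fp` (predicted positive,
#' true negative), `fn`, `tn`.
#'
#' @param predicted,truth character vectors of equal length over exactly
#'   two labels.
#' @param positive the label counted as positive.
#' @return object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(predicted, truth, positive) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth) || length(truth) == 0L)
    stopf("'predicted' and 'truth' must be nonempty and of equal length")
  labs <- unique(c(truth, predicted))
  if (length(labs) > 2L)
    stopf("labels are not binary: %s", paste(labs, collapse = ", "))
  if (!positive %in% labs && length(labs) == 2L)
    stopf("unknown positive label '%s'", positive)
  pos_p <- predicted == positive
  pos_t <- truth == positive
  confusion_counts(tp = sum(pos_p & pos_t), fp = sum(pos_p & !pos_t),
                   fn = sum(!pos_p & pos_t), tn = sum(!pos_p & !pos_t),
                   positive = positive)
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn nonnegative integer counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn, positive = "spray") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion counts must be nonnegative integers")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(predicted = c(x$positive, "other"),
                              true = c(x$positive, "other")))
  print(m)
  cat(sprintf("accuracy: %.1f%%\n", round_half_up(accuracy(x), 1)))
  invisible(x)
}

#' Classification accuracy of a confusion matrix
#'
#' `100 * (tp + tn) / (tp + fp + fn + tn)`, in percent at full precision
#' (use [round_half_up()] for one-decimal table display).
#'
#' @param cm a [confusion_matrix()].
#' @return accuracy in percent.
#' @examples
#' accuracy(confusion_counts(74, 21, 16, 79))  # 80.526...
#' @export
accuracy <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stopf("'cm' must be a confusion_matrix")
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total < 1L) stopf("accuracy undefined for an empty confusion matrix")
  100 * (cm$tp + cm$tn) / total
}

#' Summarize per-location confusion matrices
#'
#' Per-location accuracies plus two aggregates: the unweighted mean of the
#' location accuracies (the conventional "overall" figure) and the pooled
#' accuracy over the summed counts, which generally differs when location
#' totals differ.
#'
#' @param cms named list of [confusion_matrix()] objects (names =
#'   locations).
#' @return object of class `"accuracy_report"`: `table` (location, tp,
#'   fp, fn, tn, accuracy), `mean_accuracy`, `pooled_accuracy` (percent,
#'   full precision).
#' @export
summarize_locations <- function(cms) {
  if (!is.list(cms) || length(cms) == 0L)
    stopf("'cms' must be a nonempty list of confusion matrices")
  if (is.null(names(cms)))
    names(cms) <- sprintf("L%d", seq_along(cms))
  tab <- do.call(rbind, lapply(names(cms), function(nm) {
    cm <- cms[[nm]]
    data.frame(location = nm, tp = cm$tp, fp = cm$fp, fn = cm$fn,
               tn = cm$tn, accuracy = accuracy(cm))
  }))
  pooled <- confusion_counts(sum(tab$tp), sum(tab$fp), sum(tab$fn),
                             sum(tab$tn))
  structure(list(table = tab,
                 mean_accuracy = mean(tab$accuracy),
                 pooled_accuracy = accuracy(pooled)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  tab <- x$table
  tab$accuracy <- round_half_up(tab$accuracy, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("mean accuracy:   %.1f%%\npooled accuracy: %.1f%%\n",
              round_half_up(x$mean_accuracy, 1),
              round_half_up(x$pooled_accuracy, 1)))
  invisible(x)
}

#' Bundled reference confusion counts from UAV field trials
#'
#' Offline-recognition confusion counts for spray vs non-spray
#' classification reported from field trials at three locations (L1-L3),
#' separately for cropland (5 m flight height) and orchard (15 m) land
#' types.  Used as a regression fixture for the accuracy arithmetic.
#'
#' @return data frame with columns `location`, `land`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
offline_confusion_counts <- function() {
  utils::read.csv(system.file("extdata", "offline_confusion_counts.csv",
                              package = "msmrec"),
                  stringsAsFactors = FALSE)
}

#' Write an accuracy report as CSV
#'
#' @param report an `"accuracy_report"`.
#' @param path output CSV path.
#' @export
write_accuracy_report <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  utils::write.csv(report$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
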