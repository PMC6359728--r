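#' Split an ordered sequence into first (training) and last (testing) half
#'
#' The offline evaluation convention: the first half of a recorded
#' sequence trains the classifier and the last half tests it.  For odd
#' lengths the default puts the extra frame in the testing half
#' (`direction = "floor"`, e.g. 107 frames -> 53 train / 54 test);
#' `"ceil"` puts it in the training half.
#'
#' @param x a numeric matrix (rows in stream order), a [frame_stream()],
#'   or a vector.
#' @param direction where the middle frame of an odd-length sequence goes.
#' @return list with elements `train` and `test` of the same type as `x`.
#' @export
split_first_last_half <- function(x, direction = c("floor", "ceil")) {
  direction <- match.arg(direction)
  n <- if (inherits(x, "frame_stream")) length(x$frames)
       else if (is.matrix(x)) nrow(x) else length(x)
  if (n < 2L) stopf("need at least 2 frames to split")
  n_train <- if (direction == "floor") n %/% 2L else (n + 1L) %/% 2L
  take <- function(idx) {
    if (inherits(x, "frame_stream")) subset_stream(x, idx)
    else if (is.matrix(x)) x[idx, , drop = FALSE]
    else x[idx]
  }
  list(train = take(seq_len(n_train)),
       test = take(seq.int(n_train + 1L, n)))
}

#' Offline train/test protocol
#'
#' Runs the full offline evaluation on per-category ordered frame
#' sequences: each category's sequence is split first-half/last-half,
#' reference subspaces are fitted on the training halves, and the testing
#' halves are classified.  By default each test image is scored
#' individually by single-pattern similarity (`mode = "image"`, matching
#' per-image confusion counts); `mode = "set"` groups consecutive test
#' images into sets of `set_size` and classifies each set by canonical
#' angles between subspaces.
#'
#' @param x named list of per-category pattern matrices (rows in stream
#'   order), or one matrix with `labels`.
#' @param labels per-row category labels when `x` is a matrix; within each
#'   category, rows must be in stream order.
#' @param mode `"image"` (per-image scoring) or `"set"`.
#' @param set_size test-set group size for `mode = "set"` (default 4).
#' @param direction odd-length split convention, see
#'   [split_first_last_half()].
#' @param positive category treated as the positive (spray) class in the
#'   confusion matrix; default: the first category.
#' @param ... further arguments (`dim`, `tau`, `centered`) passed to
#'   [msm()].
#' @return list of class `"msm_offline"`: `model`, `predictions` (data
#'   frame with `truth` and `predicted`), `confusion` (binary case only),
#'   `accuracy` (percent).
#' @export
offline_protocol <- function(x, labels = NULL, mode = c("image", "set"),
                             set_size = 4L, direction = "floor",
                             positive = NULL, ...) {
  mode <- match.arg(mode)
  if (!is.list(x) || is.data.frame(x)) {
    x <- as_pattern_matrix(x)
    if (is.null(labels) || length(labels) != nrow(x))
      stopf("'labels' must give one category per row of 'x'")
    x <- lapply(split(seq_len(nrow(x)), factor(labels, unique(labels))),
                function(i) x[i, , drop = FALSE])
  }
  halves <- lapply(x, split_first_last_half, direction = direction)
  model <- msm(lapply(halves, `[[`, "train"), ...)

  truth <- character(0); predicted <- character(0)
  for (nm in names(halves)) {
    te <- halves[[nm]]$test
    if (mode == "image") {
      pr <- predict(model, te, type = "image")$predicted
      truth <- c(truth, rep(nm, nrow(te)))
      predicted <- c(predicted, pr)
    } else {
      starts <- seq.int(1L, nrow(te), by = set_size)
      for (s in starts) {
        idx <- s:min(s + set_size - 1L, nrow(te))
        r <- suppressMessages(classify_set(model, te[idx, , drop = FALSE]))
        truth <- c(truth, nm)
        predicted <- c(predicted, r$predicted)
      }
    }
  }
  preds <- data.frame(truth = truth, predicted = predicted)
  cm <- if (length(x) == 2L)
    confusion_matrix(predicted, truth,
                     positive = if (is.null(positive)) names(x)[1L]
                                else positive)
  else NULL
  structure(list(model = model, predictions = preds, confusion = cm,
                 accuracy = 100 * mean(truth == predicted), mode = mode),
            class = "msm_offline")
}

#' @export
print.msm_offline <- function(x, ...) {
  cat(sprintf("Offline protocol (%s mode): accuracy %.1f%% on %d test %s\n",
              x$mode, x$accuracy, nrow(x$predictions),
              if (x$mode == "image") "images" else "sets"))
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}
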