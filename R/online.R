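#' Sliding windows over an ordered pattern stream
#'
#' Overlapping windows of `w` consecutive positions with step `stride`;
#' `(n - w) %/% stride + 1` windows in total.  Four consecutive frames per
#' window is the working default of the online recognition system.
#'
#' @param n stream length, or a matrix whose row count is used.
#' @param w window length (default 4).
#' @param stride step between window starts (default 1, fully
#'   overlapping).
#' @return integer matrix with one row per window holding the `w` stream
#'   positions (1-based); zero rows, with a notice, when `n < w`.
#' @export
sliding_windows <- function(n, w = 4L, stride = 1L) {
  if (is.matrix(n)) n <- nrow(n)
  if (!is.numeric(n) || n < 0) stopf("'n' must be a nonnegative length")
  if (!is_count(w) || !is_count(stride))
    stopf("'w' and 'stride' must be positive integers")
  if (n < w) {
    message(sprintf("stream of %d frames is shorter than the window (%d)",
                    n, w))
    return(matrix(integer(0), 0L, w))
  }
  starts <- seq.int(1L, n - w + 1L, by = stride)
  t(vapply(starts, function(s) seq.int(s, s + w - 1L), integer(w)))
}

#' Online sliding-window stream classification
#'
#' Classifies a preprocessed frame stream window by window: each window of
#' `w` consecutive pattern vectors spans a query subspace that is compared
#' with every reference subspace by canonical angles, and the window is
#' assigned to the most similar category.  The stream is expected to be
#' already subsampled ([extract_frames()]) and noise-filtered
#' ([remove_noise_frames()]).  Per-window wall-clock time of the
#' similarity computation is recorded for throughput reporting.
#'
#' @param model an [msm()] fit.
#' @param x numeric matrix of pattern vectors in stream order, or a
#'   [frame_stream()] (then it is vectorized with the model's
#'   preprocessing size).
#' @param w,stride window length and step (defaults 4 and 1).
#' @param aggregation,t see [msm_similarity()].
#' @return a data frame of class `"msm_trace"`: `window_start` (0-based
#'   stream position), `predicted`, one similarity column per category,
#'   `elapsed` (seconds).  Zero rows with a notice when the stream is
#'   shorter than `w`.
#' @export
online_classify <- function(model, x, w = 4L, stride = 1L,
                            aggregation = "first", t = 2L) {
  stopifnot(inherits(model, "msm"))
  if (inherits(x, "frame_stream")) x <- vectorize_stream(x, model$config$size)
  x <- as_pattern_matrix(x)
  if (ncol(x) != model$k)
    stopf("pattern dimension %d does not match model dimension %d",
          ncol(x), model$k)
  win <- sliding_windows(nrow(x), w, stride)
  M <- length(model$classes)
  sims <- matrix(NA_real_, nrow(win), M, dimnames = list(NULL, model$classes))
  predicted <- character(nrow(win))
  elapsed <- numeric(nrow(win))
  for (i in seq_len(nrow(win))) {
    xi <- x[win[i, ], , drop = FALSE]
    Sq <- query_subspace(xi, model$config)
    t0 <- proc.time()[["elapsed"]]
    s <- vapply(model$subspaces,
                function(S) msm_similarity(Sq, S, aggregation, t), numeric(1))
    elapsed[i] <- proc.time()[["elapsed"]] - t0
    sims[i, ] <- s
    predicted[i] <- pick_class(s)$label
  }
  out <- data.frame(window_start = win[, 1L] - 1L, predicted = predicted,
                    sims, elapsed = elapsed, check.names = FALSE)
  class(out) <- c("msm_trace", "data.frame")
  out
}

#' Plot an online similarity trace
#'
#' Per-category similarity against window position, the online monitor's
#' similarity plot.
#'
#' @param x an `"msm_trace"` from [online_classify()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.msm_trace <- function(x, ...) {
  cls <- setdiff(names(x), c("window_start", "predicted", "elapsed"))
  graphics::matplot(x$window_start, as.matrix(x[cls]), type = "l", lty = 1,
                    xlab = "window start", ylab = "similarity (cos^2)",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = cls, lty = 1,
                   col = seq_along(cls))
  invisible(x)
}
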