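#' Fit a mutual subspace method classifier
#'
#' Learns one reference subspace per category by principal component
#' analysis of that category's pattern vectors (the learning phase of the
#' recognition system).  Classification of new material then compares a
#' query -- a single pattern vector or a subspace built from an image set
#' -- against each reference subspace by canonical angles; see
#' [predict.msm()], [classify_set()] and [online_classify()].
#'
#' @param x numeric matrix of training pattern vectors (one per row,
#'   typically 64 columns from 8x8 frames), or a named list of per-class
#'   matrices (then `labels` is ignored).
#' @param labels category label for each row of `x`.
#' @param dim fixed reference-subspace dimension, or `NULL` to select by
#'   cumulative contribution rate.
#' @param tau contribution-rate threshold used when `dim` is `NULL`
#'   (default 0.95).
#' @param centered use covariance about the class centroid instead of the
#'   raw autocorrelation matrix.  Default `FALSE`, the classic
#'   CLAFIC/MSM convention.
#' @param keep_data store the per-class training matrices in the fit (needed
#'   by [residuals.msm()]; cheap at pattern dimension 64).
#' @return an object of class `"msm"` with components `classes`,
#'   `subspaces` (named list of [fit_subspace()] results), `counts`,
#'   `k`, `config` (dim rule, centering, preprocessing size) and `call`.
#' @examples
#' a <- matrix(rnorm(40, mean = 5), 10, 4)
#' b <- matrix(rnorm(40, mean = -5), 10, 4)
#' fit <- msm(rbind(a, b), rep(c("spray", "nonspray"), each = 10))
#' predict(fit, a[1:4, ])
#' @export
msm <- function(x, labels = NULL, dim = NULL, tau = 0.95, centered = FALSE,
                keep_data = TRUE) {
  cl <- match.call()
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x)) || any(names(x) == ""))
      stopf("a list 'x' must be named by category")
    groups <- lapply(x, as_pattern_matrix)
  } else {
    x <- as_pattern_matrix(x)
    if (is.null(labels) || length(labels) != nrow(x))
      stopf("'labels' must give one category per row of 'x'")
    labels <- as.character(labels)
    groups <- lapply(split(seq_len(nrow(x)), factor(labels, unique(labels))),
                     function(i) x[i, , drop = FALSE])
  }
  if (length(groups) < 1L) stopf("no categories to train on")
  if (length(groups) < 2L)
    warning("only one category: the model will always predict it",
            call. = FALSE)
  ks <- vapply(groups, ncol, integer(1))
  if (length(unique(ks)) != 1L)
    stopf("all categories must share one pattern dimension")
  for (nm in names(groups))
    if (nrow(groups[[nm]]) < 2L)
      stopf("category '%s' has fewer than 2 training vectors", nm)
  subspaces <- lapply(groups, fit_subspace, dim = dim, tau = tau,
                      centered = centered)
  structure(list(classes = names(groups),
                 subspaces = subspaces,
                 counts = vapply(groups, nrow, integer(1)),
                 k = ks[[1L]],
                 config = list(dim = dim, tau = tau, centered = centered,
                               size = as.integer(round(sqrt(ks[[1L]])))),
                 data = if (keep_data) groups else NULL,
                 call = cl),
            class = "msm")
}

# Fit the query-side subspace for an image set, clamping the dimension to
# the window rank silently (a 4-frame window has rank <= 4; identical
# frames collapse it further).
query_subspace <- function(x, config) {
  d <- config$dim
  if (!is.null(d)) d <- min(d, nrow(x))
  suppressWarnings(fit_subspace(x, dim = d, tau = config$tau,
                                centered = config$centered))
}

# Argmax with first-in-model-order tie-breaking; ties within tol noted.
pick_class <- function(sims, tol = 1e-12) {
  best <- which.max(sims)
  tie <- sum(sims >= sims[best] - tol) > 1L
  list(label = names(sims)[best], tie = tie)
}

#' Classify one image set against the reference model
#'
#' Builds a subspace from the set of pattern vectors and assigns the
#' category whose reference subspace shares the smallest canonical angles
#' (highest similarity).  A single-vector input cannot span a subspace of
#' its own, so it falls back to the single-pattern similarity
#' [sm_similarity()] with a notice.  Ties are broken toward the first
#' category in model order and flagged.
#'
#' @param model an [msm()] fit.
#' @param x numeric matrix of pattern vectors (rows), or a single vector.
#' @param aggregation,t canonical-angle aggregation, see
#'   [msm_similarity()].
#' @return list of class `"msm_result"`: `predicted`, `similarities`
#'   (named, in \[0, 1\]), `method` (`"msm"` or `"sm"`), `tie`, `n`.
#' @export
classify_set <- function(model, x, aggregation = "first", t = 2L) {
  stopifnot(inherits(model, "msm"))
  x <- as_pattern_matrix(x)
  if (ncol(x) != model$k)
    stopf("pattern dimension %d does not match model dimension %d",
          ncol(x), model$k)
  if (nrow(x) == 1L) {
    message("single pattern vector: using single-pattern (SM) similarity")
    sims <- vapply(model$subspaces, function(S) sm_similarity(x[1L, ], S),
                   numeric(1))
    method <- "sm"
  } else {
    Sq <- query_subspace(x, model$config)
    sims <- vapply(model$subspaces,
                   function(S) msm_similarity(Sq, S, aggregation, t),
                   numeric(1))
    method <- "msm"
  }
  pick <- pick_class(sims)
  if (pick$tie) message("similarity tie: keeping first category in model order")
  structure(list(predicted = pick$label, similarities = sims,
                 method = method, tie = pick$tie, n = nrow(x)),
            class = "msm_result")
}

#' @export
print.msm_result <- function(x, ...) {
  cat(sprintf("Predicted: %s (%s on %d pattern%s)\n", x$predicted,
              toupper(x$method), x$n, if (x$n == 1L) "" else "s"))
  print(round(x$similarities, 4))
  invisible(x)
}

#' Predict method for MSM fits
#'
#' @param object an [msm()] fit.
#' @param newdata numeric matrix of pattern vectors (rows).
#' @param type `"set"` classifies all rows as one image set
#'   ([classify_set()]); `"image"` scores each row separately by
#'   single-pattern similarity; `"window"` classifies overlapping
#'   sliding windows ([online_classify()]).
#' @param w,stride sliding-window length and step for `type = "window"`.
#' @param aggregation,t see [msm_similarity()].
#' @param ... unused.
#' @return `"set"`: an `"msm_result"`; `"image"`: a data frame with one
#'   row per pattern (`predicted` plus one similarity column per class);
#'   `"window"`: an `"msm_trace"` data frame.
#' @export
predict.msm <- function(object, newdata, type = c("set", "image", "window"),
                        w = 4L, stride = 1L, aggregation = "first", t = 2L,
                        ...) {
  type <- match.arg(type)
  newdata <- as_pattern_matrix(newdata)
  if (ncol(newdata) != object$k)
    stopf("pattern dimension %d does not match model dimension %d",
          ncol(newdata), object$k)
  if (type == "set")
    return(classify_set(object, newdata, aggregation, t))
  if (type == "window")
    return(online_classify(object, newdata, w = w, stride = stride,
                           aggregation = aggregation, t = t))
  sims <- t(apply(newdata, 1L, function(p)
    vapply(object$subspaces, function(S) sm_similarity(p, S), numeric(1))))
  colnames(sims) <- object$classes
  predicted <- object$classes[max.col(sims, ties.method = "first")]
  data.frame(predicted = predicted, sims, check.names = FALSE)
}

#' @export
print.msm <- function(x, ...) {
  cat("Mutual subspace method classifier\n")
  cat(sprintf("  %d categories, pattern dimension k = %d, %s\n",
              length(x$classes), x$k,
              if (x$config$centered) "centered" else "uncentered"))
  for (nm in x$classes)
    cat(sprintf("  %-12s n = %3d, d = %d (contribution %.3f)\n", nm,
                x$counts[[nm]], x$subspaces[[nm]]$dim,
                x$subspaces[[nm]]$contribution_rate))
  invisible(x)
}

#' @export
summary.msm <- function(object, ...) {
  M <- length(object$classes)
  cross <- matrix(NA_real_, M, M, dimnames = list(object$classes,
                                                  object$classes))
  for (i in seq_len(M))
    for (j in seq_len(M))
      cross[i, j] <- canonical_cosines(object$subspaces[[i]],
                                       object$subspaces[[j]])[1L]
  structure(list(fit = object, cross_cosines = cross), class = "summary.msm")
}

#' @export
print.summary.msm <- function(x, ...) {
  print(x$fit)
  cat("First canonical cosine between reference subspaces:\n")
  print(round(x$cross_cosines, 4))
  invisible(x)
}

#' @export
coef.msm <- function(object, ...) {
  lapply(object$subspaces, function(S)
    list(dim = S$dim, eigenvalues = S$eigenvalues,
         contribution_rate = S$contribution_rate))
}

#' Training-pattern reconstruction residuals
#'
#' L2 norm of each stored training vector minus its projection onto its
#' own class reference subspace -- the part of the pattern the subspace
#' model does not explain.  Requires `keep_data = TRUE` at fit time.
#'
#' @param object an [msm()] fit.
#' @param ... unused.
#' @return numeric vector of residual norms, named by category.
#' @export
residuals.msm <- function(object, ...) {
  if (is.null(object$data))
    stopf("fit was created with keep_data = FALSE; residuals unavailable")
  res <- unlist(lapply(object$classes, function(nm) {
    S <- object$subspaces[[nm]]
    X <- object$data[[nm]]
    if (!is.null(S$center)) X <- sweep(X, 2L, S$center)
    R <- X - X %*% S$basis %*% t(S$basis)
    r <- sqrt(rowSums(R^2))
    names(r) <- rep(nm, length(r))
    r
  }))
  res
}

#' Simulate pattern vectors from a fitted class subspace model
#'
#' Draws Gaussian pattern vectors whose second moments match a class's
#' fitted subspace model: coefficients `N(0, lambda_i)` along the retained
#' eigenvectors (added to the class centroid for a centered fit).  Useful
#' for parametric-bootstrap style checks of the classifier.
#'
#' @param object an [msm()] fit.
#' @param nsim number of vectors to draw.
#' @param seed optional integer seed.
#' @param class category to simulate from (default: first).
#' @param ... unused.
#' @return `nsim` x k numeric matrix.
#' @export
simulate.msm <- function(object, nsim = 1L, seed = NULL,
                         class = object$classes[1L], ...) {
  S <- object$subspaces[[class]]
  if (is.null(S)) stopf("unknown category '%s'", class)
  draw <- function() {
    Z <- matrix(stats::rnorm(nsim * S$dim), nsim, S$dim)
    X <- Z %*% (t(S$basis) * sqrt(S$eigenvalues))
    if (!is.null(S$center)) X <- sweep(X, 2L, S$center, `+`)
    X
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Scree / contribution plot of the reference subspaces
#'
#' @param x an [msm()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.msm <- function(x, ...) {
  nmax <- max(vapply(x$subspaces, function(S) length(S$all_eigenvalues),
                     integer(1)))
  E <- vapply(x$subspaces, function(S) {
    ev <- S$all_eigenvalues / sum(S$all_eigenvalues)
    length(ev) <- nmax
    ev
  }, numeric(nmax))
  graphics::matplot(E, type = "b", pch = seq_along(x$classes), log = "y",
                    xlab = "component", ylab = "eigenvalue fraction", ...)
  graphics::legend("topright", legend = x$classes,
                   pch = seq_along(x$classes), col = seq_along(x$classes))
  invisible(x)
}
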