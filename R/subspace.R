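#' Autocorrelation (second-moment) matrix of a pattern-vector collection
#'
#' Computes `C = (1/n) * sum_j x_j x_j^T` over the rows of `x`.  With
#' `centered = TRUE` the row mean is subtracted first, making `C` the
#' sample covariance (denominator n).  `C` is the matrix whose leading
#' eigenvectors define a class subspace.
#'
#' @param x numeric matrix, one pattern vector per row.
#' @param centered subtract the centroid first?  The classic CLAFIC
#'   convention is uncentered (default); see [fit_subspace()].
#' @return k x k symmetric positive semidefinite matrix with attributes
#'   `n_samples` and `centered`.
#' @export
autocorrelation <- function(x, centered = FALSE) {
  x <- as_pattern_matrix(x)
  n <- nrow(x)
  if (centered) x <- sweep(x, 2L, colMeans(x))
  C <- crossprod(x) / n
  C <- (C + t(C)) / 2  # enforce exact symmetry
  attr(C, "n_samples") <- n
  attr(C, "centered") <- centered
  C
}

as_pattern_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (nrow(x) < 1L) stopf("need at least one pattern vector")
  if (!all(is.finite(x))) stopf("pattern vectors must be finite")
  x
}

#' Fit a class subspace by principal component analysis
#'
#' Eigen-decomposes the autocorrelation (or covariance) matrix of the
#' input patterns and retains the leading eigenvectors as an orthonormal
#' subspace basis.  The dimension is chosen either directly (`dim`) or as
#' the smallest d whose cumulative contribution rate
#' `sum(lambda[1:d]) / sum(lambda)` reaches `tau`.
#'
#' A requested `dim` larger than the numerical rank (eigenvalues below
#' `1e-12 * lambda_max` count as zero) is clamped to the rank with a
#' warning; the clamp is recorded in the returned object.  Eigenvalue ties
#' are resolved by the eigen solver's stable ordering; a subspace spanning
#' a tied eigenvalue block is only defined up to rotation within the block,
#' and every similarity computed from it is invariant to that rotation.
#'
#' @param x numeric matrix of pattern vectors (rows), or a precomputed
#'   matrix from [autocorrelation()] (then `centered` is taken from it).
#' @param dim fixed subspace dimension, or `NULL` to use `tau`.
#' @param tau cumulative contribution-rate threshold in (0, 1\];
#'   default 0.95.
#' @param centered passed to [autocorrelation()].
#' @return an object of class `"subspace"`: `basis` (k x d,
#'   column-orthonormal), `eigenvalues` (retained, nonincreasing),
#'   `all_eigenvalues`, `dim`, `k`, `contribution_rate`, `centered`,
#'   `center` (centroid when centered, else `NULL`), `n_samples`,
#'   `clamped`.
#' @examples
#' X <- rbind(c(1, 0, 0), c(1, 0.1, 0), c(1, -0.1, 0))
#' S <- fit_subspace(X, tau = 0.99)
#' S$dim
#' @export
fit_subspace <- function(x, dim = NULL, tau = 0.95, centered = FALSE) {
  if (is.matrix(x) && isTRUE(nrow(x) == ncol(x)) &&
      !is.null(attr(x, "n_samples"))) {
    C <- x
    centered <- attr(C, "centered")
    center <- attr(C, "center")
    n <- attr(C, "n_samples")
  } else {
    x <- as_pattern_matrix(x)
    center <- if (centered) colMeans(x) else NULL
    C <- autocorrelation(x, centered = centered)
    n <- nrow(x)
  }
  k <- ncol(C)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  total <- sum(ev)
  if (total <= 0)
    stopf("degenerate input: zero autocorrelation matrix (all patterns zero%s)",
          if (isTRUE(centered)) " after centering" else "")
  rank <- sum(ev > 1e-12 * ev[1L])
  clamped <- FALSE
  if (!is.null(dim)) {
    if (!is_count(dim) || dim > k)
      stopf("'dim' must be an integer in [1, %d]", k)
    d <- as.integer(dim)
    if (d > rank) {
      warning(sprintf("requested dim %d exceeds numerical rank %d; clamped",
                      d, rank), call. = FALSE)
      d <- rank
      clamped <- TRUE
    }
  } else {
    if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
      stopf("'tau' must lie in (0, 1]")
    cum <- cumsum(ev) / total
    d <- which(cum >= tau - 1e-12)[1L]
    d <- min(d, rank)
    d <- max(d, 1L)
  }
  structure(list(basis = e$vectors[, seq_len(d), drop = FALSE],
                 eigenvalues = ev[seq_len(d)],
                 all_eigenvalues = ev,
                 dim = d, k = k,
                 contribution_rate = sum(ev[seq_len(d)]) / total,
                 centered = isTRUE(centered), center = center,
                 n_samples = n, clamped = clamped),
            class = "subspace")
}

#' @export
print.subspace <- function(x, ...) {
  cat(sprintf("Subspace: d = %d in R^%d (%scontribution rate %.4f, n = %d)\n",
              x$dim, x$k, if (x$centered) "centered, " else "",
              x$contribution_rate, x$n_samples))
  invisible(x)
}

basis_of <- function(s) {
  if (inherits(s, "subspace")) return(s$basis)
  if (is.matrix(s)) return(s)
  stopf("expected a subspace object or an orthonormal basis matrix")
}

#' Canonical (principal) cosines between two subspaces
#'
#' The cosines of the canonical angles between the subspaces spanned by
#' two column-orthonormal bases: the singular values of `t(B_P) %*% B_Q`,
#' clipped to \[0, 1\] and sorted nonincreasing.  The first is the cosine
#' of the smallest angle -- the maximum of `u' v` over unit vectors `u` in
#' P and `v` in Q.
#'
#' @param P,Q `"subspace"` objects (or bare column-orthonormal matrices)
#'   over the same ambient dimension.
#' @return numeric vector of length `min(d_P, d_Q)`.
#' @export
canonical_cosines <- function(P, Q) {
  Bp <- basis_of(P); Bq <- basis_of(Q)
  if (nrow(Bp) != nrow(Bq))
    stopf("subspaces live in different ambient dimensions (%d vs %d)",
          nrow(Bp), nrow(Bq))
  s <- svd(crossprod(Bp, Bq), nu = 0, nv = 0)$d
  sort(pmin(pmax(s, 0), 1), decreasing = TRUE)
}

#' Single-pattern subspace-method (CLAFIC) similarity
#'
#' The squared cosine of the angle between a pattern vector and a class
#' subspace: `sum_i (p . phi_i)^2 / ||p||^2`, i.e. the squared norm of the
#' projection of the normalized pattern onto the subspace.  For a centered
#' subspace the stored centroid is subtracted from `p` first.
#'
#' @param p nonzero numeric pattern vector of length k.
#' @param S a `"subspace"` object.
#' @return similarity in \[0, 1\].
#' @export
sm_similarity <- function(p, S) {
  if (!inherits(S, "subspace")) stopf("'S' must be a subspace object")
  p <- as.numeric(p)
  if (length(p) != S$k)
    stopf("pattern length %d does not match ambient dimension %d",
          length(p), S$k)
  if (!is.null(S$center)) p <- p - S$center
  nrm2 <- sum(p^2)
  if (nrm2 == 0) stopf("zero pattern vector has no direction")
  min(1, sum(crossprod(S$basis, p)^2) / nrm2)
}

#' Mutual subspace method similarity between two subspaces
#'
#' Similarity of two pattern sets represented by their subspaces, as a
#' function of the canonical angles.  `aggregation = "first"` returns
#' `cos^2` of the smallest canonical angle (the classic MSM similarity);
#' `"mean_top"` returns the mean of the `t` largest squared cosines, which
#' uses more angles and is less sensitive to a single shared direction.
#' The squared-cosine scale makes MSM directly comparable with
#' [sm_similarity()]: for a one-dimensional input subspace the two agree.
#'
#' @param P,Q `"subspace"` objects over the same ambient dimension.
#' @param aggregation `"first"` or `"mean_top"`.
#' @param t number of angles averaged when `aggregation = "mean_top"`.
#' @return similarity in \[0, 1\].
#' @export
msm_similarity <- function(P, Q, aggregation = c("first", "mean_top"), t = 2L) {
  aggregation <- match.arg(aggregation)
  cos2 <- canonical_cosines(P, Q)^2
  if (aggregation == "first") return(cos2[1L])
  if (!is_count(t) || t > length(cos2))
    stopf("'t' must be a positive integer <= %d canonical angles", length(cos2))
  mean(cos2[seq_len(t)])
}
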