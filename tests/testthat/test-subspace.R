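e_k <- function(i, k) { v <- numeric(k); v[i] <- 1; v }

test_that("autocorrelation matches hand-evaluated second moments", {
  # single unit vector e1
  C <- autocorrelation(matrix(e_k(1, 4), 1))
  expect_equal(unclass(C)[1:4, 1:4], diag(c(1, 0, 0, 0)),
               ignore_attr = TRUE)
  # centering removes a single sample entirely
  C0 <- autocorrelation(matrix(rnorm(4), 1), centered = TRUE)
  expect_equal(max(abs(C0)), 0)
  # {e1, e2} -> diag(1/2, 1/2, 0)
  C2 <- autocorrelation(rbind(e_k(1, 3), e_k(2, 3)))
  expect_equal(C2, diag(c(0.5, 0.5, 0)), ignore_attr = TRUE)
  # symmetric PSD on random data
  X <- matrix(rnorm(50 * 6), 50)
  C3 <- autocorrelation(X, centered = TRUE)
  expect_equal(C3, t(C3), ignore_attr = TRUE)
  expect_gte(min(eigen(C3, symmetric = TRUE)$values), -1e-10 * sum(diag(C3)))
  expect_error(autocorrelation(matrix(numeric(0), 0, 3)), "at least one")
})

test_that("subspace fitting selects dimension by contribution rate", {
  # rank-1 data -> d = 1, basis +-e1
  X1 <- matrix(rep(e_k(1, 5), 10), 10, byrow = TRUE)
  S1 <- fit_subspace(X1, tau = 0.95)
  expect_identical(S1$dim, 1L)
  expect_equal(abs(S1$basis[, 1]), e_k(1, 5))
  # data with exact second-moment eigenvalues (4, 1, 0): tau = 0.8 -> d = 1
  X2 <- rbind(c(2, 1, 0), c(2, -1, 0), c(-2, 1, 0), c(-2, -1, 0))
  S2 <- fit_subspace(X2, tau = 0.8)
  expect_identical(S2$dim, 1L)
  expect_equal(S2$contribution_rate, 0.8)
  expect_equal(S2$all_eigenvalues, c(4, 1, 0))
  # direct eigen-decomposition oracle on the same autocorrelation matrix
  oracle <- eigen(crossprod(X2) / 4, symmetric = TRUE)
  expect_equal(abs(sum(S2$basis[, 1] * oracle$vectors[, 1])), 1)
  # tau slightly above 0.8 needs the second component
  expect_identical(fit_subspace(X2, tau = 0.81)$dim, 2L)
  # tau = 1 on full-rank data keeps the full rank
  X3 <- matrix(rnorm(40), 10, 4)
  S3 <- fit_subspace(X3, tau = 1)
  expect_identical(S3$dim, 4L)
  expect_equal(S3$contribution_rate, 1)
})

test_that("fitted bases are orthonormal and rank requests are clamped", {
  X <- matrix(rnorm(30), 10, 3)
  S <- fit_subspace(X, tau = 1)
  expect_equal(crossprod(S$basis), diag(S$dim), tolerance = 1e-10)
  # rank-deficient data: requested dim clamps with a warning
  X2 <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_warning(S2 <- fit_subspace(X2, dim = 3), "clamped")
  expect_identical(S2$dim, 1L)
  expect_true(S2$clamped)
  expect_error(fit_subspace(matrix(0, 4, 3)), "degenerate")
  expect_error(fit_subspace(X, dim = 9), "must be an integer")
  expect_error(fit_subspace(X, tau = 0), "0, 1")
})

test_that("canonical cosines match analytic constructions", {
  B <- random_basis(8, 3)
  expect_equal(canonical_cosines(B, B), rep(1, 3), tolerance = 1e-12)
  expect_equal(canonical_cosines(matrix(e_k(1, 4)), matrix(e_k(2, 4))), 0)
  # plane family: span{e1,e2} vs span{e1, cos(a) e2 + sin(a) e3}
  for (a in seq(0.1, 1.5, length.out = 10)) {
    P <- cbind(e_k(1, 5), e_k(2, 5))
    Q <- cbind(e_k(1, 5), cos(a) * e_k(2, 5) + sin(a) * e_k(3, 5))
    expect_equal(canonical_cosines(P, Q), c(1, cos(a)), tolerance = 1e-12)
  }
  expect_error(canonical_cosines(random_basis(4, 2), random_basis(5, 2)),
               "ambient")
})

test_that("SVD cosines agree with the alternating-projection oracle", {
  set.seed(101)
  for (i in 1:20) {
    k <- sample(6:20, 1)
    Bp <- random_basis(k, sample(1:5, 1))
    Bq <- random_basis(k, sample(1:5, 1))
    expect_equal(canonical_cosines(Bp, Bq)[1], oracle_first_cosine(Bp, Bq),
                 tolerance = 1e-6)
  }
})

test_that("single-pattern similarity is the squared projection cosine", {
  S <- as_subspace(matrix(e_k(1, 4)))
  expect_equal(sm_similarity(e_k(1, 4) * 3, S), 1)
  expect_equal(sm_similarity(e_k(2, 4), S), 0)
  expect_equal(sm_similarity(c(1, 1, 0, 0) / sqrt(2), S), 0.5)
  expect_error(sm_similarity(numeric(4), S), "zero pattern")
  # scale invariance
  p <- rnorm(4)
  expect_equal(sm_similarity(p, S), sm_similarity(10 * p, S))
})

test_that("subspace similarity aggregates squared canonical cosines", {
  B <- random_basis(6, 2)
  expect_equal(msm_similarity(B, B), 1)
  expect_equal(msm_similarity(matrix(e_k(1, 4)), matrix(e_k(2, 4))), 0)
  a <- 0.7
  P <- cbind(e_k(1, 5), e_k(2, 5))
  Q <- cbind(e_k(1, 5), cos(a) * e_k(2, 5) + sin(a) * e_k(3, 5))
  expect_equal(msm_similarity(P, Q, "first"), 1)
  expect_equal(msm_similarity(P, Q, "mean_top", t = 2), (1 + cos(a)^2) / 2)
  expect_error(msm_similarity(P, Q, "mean_top", t = 3), "canonical angles")
})

test_that("similarity is a function of the subspace, not the basis", {
  set.seed(7)
  for (i in 1:25) {
    k <- sample(8:16, 1)
    dp <- sample(2:4, 1); dq <- sample(2:4, 1)
    Bp <- random_basis(k, dp); Bq <- random_basis(k, dq)
    s <- msm_similarity(Bp, Bq)
    expect_equal(msm_similarity(Bp %*% random_rotation(dp),
                                Bq %*% random_rotation(dq)), s,
                 tolerance = 1e-10)
    expect_equal(msm_similarity(Bq, Bp), s, tolerance = 1e-10)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("single-pattern and set similarity agree on one-dim inputs", {
  set.seed(21)
  for (i in 1:10) {
    p <- rnorm(6)
    S <- fit_subspace(matrix(rnorm(5 * 6), 5), tau = 0.99)
    expect_equal(sm_similarity(p, S),
                 msm_similarity(matrix(p / sqrt(sum(p^2))), S),
                 tolerance = 1e-12)
  }
})

test_that("noiseless planted subspaces are recovered exactly", {
  set.seed(33)
  k <- 20; d <- 4
  B <- random_basis(k, d)
  X <- matrix(rnorm(60 * d), 60) %*% t(B)  # 60 points in span(B)
  S <- fit_subspace(X, dim = d)
  # measure the largest principal angle through its sine (the residual of
  # B after projection onto the fit); acos() cannot resolve angles below
  # ~1e-8 since cos(theta) ~ 1 - theta^2/2 underflows double precision
  resid <- B - S$basis %*% crossprod(S$basis, B)
  worst_angle <- asin(min(1, svd(resid, nu = 0, nv = 0)$d[1]))
  expect_lt(worst_angle, 1e-8)
})
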