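fit_separable <- function(n_frames = 60) {
  msm(params_to_patterns(separable_params(n_frames = n_frames)))
}

test_that("training builds one reference subspace per category", {
  fit <- fit_separable()
  expect_s3_class(fit, "msm")
  expect_identical(fit$classes, c("spray", "nonspray"))
  expect_identical(unname(fit$counts), c(60L, 60L))
  expect_identical(fit$k, 64L)
  # cross-category similarity lower than within, on held-out material
  pr <- separable_params(n_frames = 20, seed_a = 11, seed_b = 12)
  held <- params_to_patterns(pr)
  Sq <- fit_subspace(held$spray, tau = 0.95)
  expect_gt(msm_similarity(Sq, fit$subspaces$spray),
            msm_similarity(Sq, fit$subspaces$nonspray))
})

test_that("training rejects under-sized or malformed categories", {
  X <- matrix(rnorm(12), 3, 4)
  expect_error(msm(rbind(X, rnorm(4)), c("a", "a", "a", "b")),
               "category 'b'")
  expect_error(msm(list(a = X, b = matrix(rnorm(10), 2, 5))),
               "pattern dimension")
  expect_warning(msm(X, rep("a", 3)), "one category")
})

test_that("duplicated categories give coincident reference subspaces", {
  X <- matrix(rnorm(20 * 6), 20)
  fit <- msm(list(a = X, b = X), tau = 0.9)
  cc <- canonical_cosines(fit$subspaces$a, fit$subspaces$b)
  expect_equal(cc, rep(1, length(cc)), tolerance = 1e-10)
})

test_that("set classification predicts the most similar category", {
  fit <- fit_separable()
  pr <- separable_params(n_frames = 12, seed_a = 21, seed_b = 22)
  held <- params_to_patterns(pr)
  ra <- classify_set(fit, held$spray)
  rb <- classify_set(fit, held$nonspray)
  expect_identical(ra$predicted, "spray")
  expect_identical(rb$predicted, "nonspray")
  # argmax consistency
  expect_identical(ra$predicted,
                   names(which.max(ra$similarities)))
  # self-consistency: the training set itself is at least as similar to
  # its own category as to the other
  rs <- classify_set(fit, fit$data$spray)
  expect_gte(rs$similarities["spray"], rs$similarities["nonspray"])
})

test_that("single-vector queries fall back to single-pattern scoring", {
  fit <- fit_separable()
  p <- fit$data$spray[1, ]
  expect_message(r <- classify_set(fit, p), "single pattern")
  expect_identical(r$method, "sm")
  expect_equal(unname(r$similarities["spray"]),
               sm_similarity(p, fit$subspaces$spray))
})

test_that("a one-category model always predicts that category", {
  fit <- suppressWarnings(msm(matrix(rnorm(40), 10, 4), rep("only", 10)))
  r <- classify_set(fit, matrix(rnorm(12), 3, 4))
  expect_identical(r$predicted, "only")
  expect_true(r$similarities >= 0 && r$similarities <= 1)
})

test_that("category order does not change predictions", {
  pr <- separable_params(n_frames = 40)
  pats <- params_to_patterns(pr)
  f1 <- msm(pats)
  f2 <- msm(rev(pats))
  q <- params_to_patterns(separable_params(n_frames = 8, seed_a = 31,
                                           seed_b = 32))
  for (x in q) {
    expect_identical(classify_set(f1, x)$predicted,
                     classify_set(f2, x)$predicted)
  }
})

test_that("first/last-half splitting follows the stated conventions", {
  X <- matrix(0, 198, 2)
  s <- split_first_last_half(X)
  expect_identical(nrow(s$train), 99L)
  expect_identical(nrow(s$test), 99L)
  # odd length, floor-first default: 107 -> 53 train / 54 test
  s2 <- split_first_last_half(matrix(0, 107, 1))
  expect_identical(c(nrow(s2$train), nrow(s2$test)), c(53L, 54L))
  s3 <- split_first_last_half(matrix(0, 107, 1), direction = "ceil")
  expect_identical(c(nrow(s3$train), nrow(s3$test)), c(54L, 53L))
  expect_identical(lengths(split_first_last_half(1:2)),
                   c(train = 1L, test = 1L))
  expect_error(split_first_last_half(1), "at least 2")
  # no overlap, order preserved
  s4 <- split_first_last_half(1:9)
  expect_identical(c(s4$train, s4$test), 1:9)
})

test_that("sliding windows enumerate consecutive frame sets", {
  w <- sliding_windows(10, 4, 1)
  expect_identical(nrow(w), 7L)
  expect_identical(w[1, ], 1:4)
  expect_identical(w[7, ], 7:10)
  expect_identical(nrow(sliding_windows(4, 4)), 1L)
  w2 <- sliding_windows(9, 4, 2)
  expect_identical(w2[, 1], c(1L, 3L, 5L))
  expect_message(w3 <- sliding_windows(3, 4), "shorter")
  expect_identical(nrow(w3), 0L)
})

test_that("online classification labels homogeneous streams correctly", {
  fit <- fit_separable()
  q <- params_to_patterns(separable_params(n_frames = 30, seed_a = 41,
                                           seed_b = 42))
  tr <- online_classify(fit, q$spray)
  expect_identical(nrow(tr), 27L)
  expect_true(all(tr$predicted == "spray"))
  expect_true(all(tr$spray >= tr$nonspray))
  expect_true(all(tr$elapsed >= 0))
})

test_that("online predictions switch within a window of a class boundary", {
  fit <- fit_separable()
  q <- params_to_patterns(separable_params(n_frames = 30, seed_a = 51,
                                           seed_b = 52))
  stream <- rbind(q$spray, q$nonspray)
  tr <- online_classify(fit, stream, w = 4)
  pure_a <- tr$window_start <= 30 - 4      # 0-based starts fully inside A
  pure_b <- tr$window_start >= 30          # fully inside B
  expect_true(all(tr$predicted[pure_a] == "spray"))
  expect_true(all(tr$predicted[pure_b] == "nonspray"))
})

test_that("degenerate windows of identical frames are handled", {
  fit <- fit_separable()
  x <- matrix(rep(fit$data$spray[1, ], 4), 4, byrow = TRUE)
  tr <- online_classify(fit, x)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$predicted, "spray")
})

test_that("online and set classification agree on the same window", {
  fit <- fit_separable()
  x <- params_to_patterns(separable_params(n_frames = 4, seed_a = 61,
                                           seed_b = 62))$spray
  tr <- online_classify(fit, x, w = 4)
  r <- classify_set(fit, x)
  expect_identical(tr$predicted, r$predicted)
  expect_equal(unlist(tr[1, c("spray", "nonspray")]), r$similarities,
               tolerance = 1e-12)
})

test_that("fits persist to text files and round-trip exactly", {
  fit <- fit_separable(n_frames = 30)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_msm(fit, d1)
  # reproducibility: identical fits write byte-identical model files
  write_msm(fit_separable(n_frames = 30), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- read_msm(d1)
  q <- params_to_patterns(separable_params(n_frames = 6, seed_a = 71,
                                           seed_b = 72))$nonspray
  expect_equal(classify_set(back, q)$similarities,
               classify_set(fit, q)$similarities, tolerance = 1e-15)
  expect_identical(back$classes, fit$classes)
})

test_that("model methods expose spectra, residuals and simulation", {
  fit <- fit_separable(n_frames = 30)
  cf <- coef(fit)
  expect_named(cf, c("spray", "nonspray"))
  expect_true(all(vapply(cf, function(s) s$contribution_rate, 1) >= 0.95))
  res <- residuals(fit)
  expect_length(res, 60L)
  expect_true(all(res >= 0))
  sim <- simulate(fit, nsim = 5, seed = 1, class = "spray")
  expect_identical(dim(sim), c(5L, 64L))
  expect_identical(sim, simulate(fit, nsim = 5, seed = 1, class = "spray"))
  # simulated spray patterns look like spray to the classifier
  expect_identical(classify_set(fit, sim)$predicted, "spray")
  s <- summary(fit)
  expect_lt(s$cross_cosines["spray", "nonspray"], 1)
})
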