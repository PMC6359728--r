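# Shared fixtures and independent oracles.

# Random k x d column-orthonormal basis.
random_basis <- function(k, d) qr.Q(qr(matrix(rnorm(k * d), k, d)))

# Random d x d orthogonal matrix (for re-basis invariance checks).
random_rotation <- function(d) qr.Q(qr(matrix(rnorm(d * d), d, d)))

# Wrap a bare orthonormal basis as a minimal subspace object.
as_subspace <- function(B) {
  structure(list(basis = B, eigenvalues = rep(1, ncol(B)),
                 all_eigenvalues = rep(1, ncol(B)), dim = ncol(B),
                 k = nrow(B), contribution_rate = 1, centered = FALSE,
                 center = NULL, n_samples = ncol(B), clamped = FALSE),
            class = "subspace")
}

# Independent oracle for the first canonical cosine: alternating
# projection between the two subspaces (maximize u'v over unit u in P,
# v in Q by repeatedly projecting onto each subspace and renormalizing),
# with random restarts.  Never calls svd().
oracle_first_cosine <- function(Bp, Bq, tol = 1e-13, max_iter = 200000L,
                                restarts = 3L) {
  best <- 0
  for (r in seq_len(restarts)) {
    v <- rnorm(nrow(Bp))
    v <- v / sqrt(sum(v^2))
    prev <- -1
    for (i in seq_len(max_iter)) {
      u <- Bp %*% crossprod(Bp, v)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-150) { prev <- 0; break }
      u <- u / nu
      v <- Bq %*% crossprod(Bq, u)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-150) { prev <- 0; break }
      v <- v / nv
      cur <- sum(u * v)
      if (abs(cur - prev) < tol) { prev <- cur; break }
      prev <- cur
    }
    best <- max(best, prev)
  }
  best
}

# Oriented textures on the unit intensity scale: crop-row-like stripes.
# Vertical and horizontal stripes differ in direction (not just scale),
# which is the kind of contrast a subspace classifier can exploit.
vertical_stripes <- function(hi = 0.9, lo = 0.1)
  matrix(rep(c(hi, lo), length.out = 8), 8, 8, byrow = TRUE)
horizontal_stripes <- function(hi = 0.9, lo = 0.1)
  matrix(rep(c(hi, lo), length.out = 8), 8, 8)

# Standard separable two-class study fixture: 200 frames per class,
# moderate noise and temporal correlation, texture contrast far above the
# noise level.
separable_params <- function(n_frames = 200L, sd = 0.05, rho = 0.5,
                             seed_a = 1L, seed_b = 2L) {
  list(spray = scene_params("spray", vertical_stripes(),
                            within_class_sd = sd, temporal_corr = rho,
                            n_frames = n_frames, seed = seed_a),
       nonspray = scene_params("nonspray", horizontal_stripes(),
                               within_class_sd = sd, temporal_corr = rho,
                               n_frames = n_frames, seed = seed_b))
}

# Zero-separation fixture: identical templates, noise only.
chance_params <- function(n_frames = 200L, sd = 0.05, rho = 0.5,
                          seed_a = 1L, seed_b = 3L) {
  list(spray = scene_params("spray", vertical_stripes(),
                            within_class_sd = sd, temporal_corr = rho,
                            n_frames = n_frames, seed = seed_a),
       nonspray = scene_params("nonspray", vertical_stripes(),
                               within_class_sd = sd, temporal_corr = rho,
                               n_frames = n_frames, seed = seed_b))
}

params_to_patterns <- function(params)
  lapply(params, function(p) vectorize_stream(generate_scene_sequence(p)))
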