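#' Scene parameters for the synthetic aerial-frame generator
#'
#' Describes one visually homogeneous scene class (e.g. crop canopy to be
#' sprayed, or bare soil / farm structures to be avoided) as a fixed
#' appearance template plus temporally correlated Gaussian pixel noise.
#' Successive frames follow a stationary AR(1) process per pixel, the
#' simplest model with both within-class appearance spread and
#' frame-to-frame correlation -- the two properties a subspace classifier
#' actually exploits.
#'
#' @param class_id category label (character scalar).
#' @param base_pattern class mean appearance on the unit intensity scale:
#'   either a numeric vector of length 64 (an 8x8 template, row-major) or a
#'   matrix with values in \[0, 1\].  Upscaled to `frame_size` by nearest
#'   -neighbour block replication.
#' @param within_class_sd nonnegative per-pixel appearance spread (unit
#'   intensity scale).
#' @param temporal_corr AR(1) lag-1 correlation between successive frames,
#'   in \[0, 1).
#' @param frame_size integer (height, width) of generated frames.
#' @param n_frames number of frames in a sequence.
#' @param seed integer seed; identical parameters and seed reproduce
#'   bit-identical sequences.
#' @return an object of class `"scene_params"`.
#' @seealso [generate_scene_sequence()], [generate_two_class_dataset()],
#'   [flight_transition_stream()]
#' @export
scene_params <- function(class_id, base_pattern, within_class_sd = 0.08,
                         temporal_corr = 0.6, frame_size = c(64L, 64L),
                         n_frames = 10L, seed = 1L) {
  if (!is.character(class_id) || length(class_id) != 1L)
    stopf("'class_id' must be a single character label")
  if (is.numeric(base_pattern) && is.null(dim(base_pattern))) {
    if (length(base_pattern) != 64L)
      stopf("a vector 'base_pattern' must have length 64 (8x8, row-major)")
    base_pattern <- matrix(base_pattern, 8L, 8L, byrow = TRUE)
  }
  if (!is.matrix(base_pattern) || !is.numeric(base_pattern))
    stopf("'base_pattern' must be a numeric vector of length 64 or a matrix")
  if (any(base_pattern < 0 | base_pattern > 1))
    stopf("'base_pattern' values must lie in [0, 1]")
  if (!is.numeric(within_class_sd) || within_class_sd < 0)
    stopf("'within_class_sd' must be nonnegative")
  if (!is.numeric(temporal_corr) || temporal_corr < 0 || temporal_corr >= 1)
    stopf("'temporal_corr' must lie in [0, 1)")
  frame_size <- as.integer(frame_size)
  if (length(frame_size) != 2L || any(frame_size < 1L))
    stopf("'frame_size' must be two positive integers (height, width)")
  if (!is_count(n_frames))
    stopf("'n_frames' must be a positive integer")
  structure(list(class_id = class_id, base_pattern = base_pattern,
                 within_class_sd = within_class_sd,
                 temporal_corr = temporal_corr,
                 frame_size = frame_size, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "scene_params")
}

# Nearest-neighbour upscale of the template to the working frame size.
scene_template <- function(params) {
  b <- params$base_pattern
  h <- params$frame_size[1L]; w <- params$frame_size[2L]
  ri <- floor((seq_len(h) - 1L) * nrow(b) / h) + 1L
  ci <- floor((seq_len(w) - 1L) * ncol(b) / w) + 1L
  b[ri, ci, drop = FALSE]
}

# Unit-scale grayscale matrix -> 8-bit RGB raw frame (channels replicated).
gray_to_rgb_frame <- function(g) {
  px <- as.integer(round(pmin(pmax(g, 0), 1) * 255))
  array(px, dim = c(nrow(g), ncol(g), 3L))
}

#' Generate one labeled synthetic frame sequence
#'
#' Draws `n_frames` RGB frames of one scene class: the class template plus
#' stationary AR(1) Gaussian pixel noise, quantized to 8-bit.  Deterministic
#' given the seed stored in `params`; the caller's RNG state is untouched.
#'
#' @param params a [scene_params()] object.
#' @return a [frame_stream()] labeled with `params$class_id`.
#' @examples
#' p <- scene_params("spray", base_pattern = rep(0.6, 64),
#'                   within_class_sd = 0.05, n_frames = 6, seed = 7)
#' s <- generate_scene_sequence(p)
#' length(s$frames)
#' @export
generate_scene_sequence <- function(params) {
  if (!inherits(params, "scene_params"))
    stopf("'params' must be a scene_params object")
  tmpl <- scene_template(params)
  h <- nrow(tmpl); w <- ncol(tmpl)
  n <- params$n_frames
  rho <- params$temporal_corr
  sd <- params$within_class_sd
  frames <- with_seed(params$seed, {
    out <- vector("list", n)
    e <- matrix(stats::rnorm(h * w, 0, sd), h, w)
    out[[1L]] <- gray_to_rgb_frame(tmpl + e)
    if (n > 1L) {
      innov_sd <- sd * sqrt(1 - rho^2)
      for (t in 2L:n) {
        e <- rho * e + matrix(stats::rnorm(h * w, 0, innov_sd), h, w)
        out[[t]] <- gray_to_rgb_frame(tmpl + e)
      }
    }
    out
  })
  frame_stream(frames, indices = seq_len(n) - 1L, label = params$class_id,
               source_id = sprintf("synthetic:%s:seed%d", params$class_id,
                                   params$seed))
}

#' Generate a balanced labeled two-class dataset of frame sequences
#'
#' Emulates the paired spray / non-spray training collections: for each
#' class, `n_sequences_per_class` independent sequences are generated, the
#' i-th sequence of a class using seed `master_seed + i - 1` (class A) or
#' `master_seed + n_sequences_per_class + i - 1` (class B), so the whole
#' dataset is reproducible from a single master seed.
#'
#' @param params_A,params_B [scene_params()] for the two classes; their
#'   `class_id`s must differ.  Their own `seed` fields are ignored in favour
#'   of the derived per-sequence seeds.
#' @param n_sequences_per_class positive integer.
#' @param master_seed integer master seed.
#' @return list with elements `sequences` (list of [frame_stream()]s) and
#'   `labels` (character vector, one per sequence), class `"scene_dataset"`.
#' @export
generate_two_class_dataset <- function(params_A, params_B,
                                       n_sequences_per_class = 1L,
                                       master_seed = 1L) {
  if (!inherits(params_A, "scene_params") || !inherits(params_B, "scene_params"))
    stopf("'params_A' and 'params_B' must be scene_params objects")
  if (identical(params_A$class_id, params_B$class_id))
    stopf("the two classes must have distinct class_ids")
  if (!is_count(n_sequences_per_class))
    stopf("'n_sequences_per_class' must be a positive integer")
  n <- as.integer(n_sequences_per_class)
  gen <- function(params, offset) {
    lapply(seq_len(n), function(i) {
      params$seed <- as.integer(master_seed) + offset + i - 1L
      generate_scene_sequence(params)
    })
  }
  seqs <- c(gen(params_A, 0L), gen(params_B, n))
  labels <- c(rep(params_A$class_id, n), rep(params_B$class_id, n))
  structure(list(sequences = seqs, labels = labels), class = "scene_dataset")
}

#' Mark a noise segment in a flight transition
#'
#' Placeholder for frames belonging to neither class (takeoff, landing,
#' field entry/exit): unstructured uniform random pixels.
#'
#' @param n_frames positive integer segment length.
#' @export
noise_segment <- function(n_frames) {
  if (!is_count(n_frames)) stopf("'n_frames' must be a positive integer")
  structure(list(n_frames = as.integer(n_frames)), class = "noise_segment")
}

#' Simulate a flight with class segments and noise transitions
#'
#' Concatenates scene segments and noise segments into one ordered frame
#' stream with a per-frame ground-truth label (`class_id` or `"noise"`),
#' emulating a UAV flight that passes over different land covers with
#' unusable transition frames in between.
#'
#' @param segments list whose elements are [scene_params()] objects (segment
#'   length taken from their `n_frames`) or [noise_segment()] markers.
#' @param noise_intensity_range pixel-intensity interval (unit scale) for
#'   uniform random noise frames.
#' @param seed integer seed for the noise frames (scene segments use their
#'   own seeds).
#' @return list with elements `stream` (a [frame_stream()]) and `labels`
#'   (character, one per frame).
#' @export
flight_transition_stream <- function(segments, noise_intensity_range = c(0, 1),
                                     seed = 1L) {
  if (!is.list(segments) || length(segments) == 0L)
    stopf("'segments' must be a non-empty list")
  scene_segs <- Filter(function(s) inherits(s, "scene_params"), segments)
  if (length(scene_segs) == 0L)
    stopf("'segments' must contain at least one scene_params segment")
  fs <- scene_segs[[1L]]$frame_size
  if (!all(vapply(scene_segs, function(s) all(s$frame_size == fs), logical(1))))
    stopf("all scene segments must share one frame_size")
  r <- sort(noise_intensity_range)

  frames <- list(); labels <- character(0)
  noise_counter <- 0L
  for (seg in segments) {
    if (inherits(seg, "scene_params")) {
      s <- generate_scene_sequence(seg)
      frames <- c(frames, s$frames)
      labels <- c(labels, rep(seg$class_id, seg$n_frames))
    } else if (inherits(seg, "noise_segment")) {
      nf <- with_seed(as.integer(seed) + noise_counter, {
        lapply(seq_len(seg$n_frames), function(i) {
          g <- matrix(stats::runif(fs[1L] * fs[2L], r[1L], r[2L]),
                      fs[1L], fs[2L])
          gray_to_rgb_frame(g)
        })
      })
      noise_counter <- noise_counter + 1L
      frames <- c(frames, nf)
      labels <- c(labels, rep("noise", seg$n_frames))
    } else {
      stopf("segments must be scene_params or noise_segment objects")
    }
  }
  list(stream = frame_stream(frames, indices = seq_along(frames) - 1L,
                             source_id = "synthetic:flight"),
       labels = labels)
}
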