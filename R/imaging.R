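#' Construct an ordered frame stream
#'
#' A frame stream is the package's container for an ordered sequence of raw
#' frames: 8-bit RGB arrays (height x width x 3, values 0-255) together
#' with their original indices in the source video/stream, an optional
#' category label, and a source identifier.
#'
#' @param frames list of height x width x 3 numeric/integer arrays with
#'   values in \[0, 255\].
#' @param indices integer vector of original frame positions (0-based),
#'   strictly increasing; defaults to `0:(n-1)`.
#' @param label optional category label for the whole stream.
#' @param source_id optional identifier of the source.
#' @return an object of class `"frame_stream"`.
#' @export
frame_stream <- function(frames, indices = NULL, label = NULL,
                         source_id = NULL) {
  if (!is.list(frames)) stopf("'frames' must be a list of pixel arrays")
  if (is.null(indices)) indices <- seq_along(frames) - 1L
  indices <- as.integer(indices)
  if (length(indices) != length(frames))
    stopf("'indices' must have one entry per frame")
  if (length(indices) > 1L && any(diff(indices) <= 0L))
    stopf("frame indices must be strictly increasing")
  structure(list(frames = frames, indices = indices, label = label,
                 source_id = source_id),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  d <- if (length(x$frames)) paste(dim(x$frames[[1L]]), collapse = "x") else "?"
  cat(sprintf("Frame stream: %d frames (%s)%s%s\n", length(x$frames), d,
              if (is.null(x$label)) "" else paste0(", label=", x$label),
              if (is.null(x$source_id)) "" else paste0(", source=", x$source_id)))
  invisible(x)
}

#' @export
length.frame_stream <- function(x) length(x$frames)

# Subset a stream, keeping labels/source and original indices.
subset_stream <- function(stream, keep) {
  frame_stream(stream$frames[keep], indices = stream$indices[keep],
               label = stream$label, source_id = stream$source_id)
}

#' Read a directory of PNG frames as a stream
#'
#' Files are taken in lexicographic order, the convention for exported
#' frame directories; pixel values are rescaled to 0-255 and an alpha
#' channel, if present, is dropped.  Grayscale PNGs are replicated to three
#' channels so that the downstream path is uniform.
#'
#' @param path directory containing `.png` files.
#' @param label optional stream label.
#' @return a [frame_stream()].
#' @export
read_frame_dir <- function(path, label = NULL) {
  if (!dir.exists(path)) stopf("cannot read frame directory '%s'", path)
  files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stopf("no PNG frames found in '%s'", path)
  frames <- lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    if (dim(px)[3L] >= 3L) px <- px[, , 1:3, drop = FALSE]
    array(as.integer(round(px * 255)), dim = dim(px))
  })
  frame_stream(frames, label = label, source_id = path)
}

#' Subsample a frame source at a fixed interval
#'
#' Keeps the first frame and then every `sampling_interval`-th frame
#' (source positions 0, s, 2s, ...), the 1-in-20 decimation used to thin a
#' video stream before recognition.  Original indices are retained.
#'
#' @param source a [frame_stream()] or a path to a PNG frame directory.
#' @param sampling_interval positive integer s; `1` keeps every frame.
#' @return a [frame_stream()] of the kept frames.
#' @examples
#' s <- generate_scene_sequence(scene_params("a", rep(.5, 64), n_frames = 100))
#' length(extract_frames(s, 20))  # 5 frames: source indices 0,20,40,60,80
#' @export
extract_frames <- function(source, sampling_interval = 20L) {
  if (is.character(source)) source <- read_frame_dir(source)
  if (!inherits(source, "frame_stream"))
    stopf("'source' must be a frame_stream or a frame directory path")
  if (!is_count(sampling_interval))
    stopf("'sampling_interval' must be a positive integer")
  n <- length(source$frames)
  if (n == 0L) stopf("empty frame source")
  keep <- seq.int(1L, n, by = as.integer(sampling_interval))
  subset_stream(source, keep)
}

#' Convert an RGB frame to grayscale
#'
#' ITU-R BT.601 luma: `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest
#' integer on the 0-255 scale.
#'
#' @param frame height x width x 3 array, values 0-255.
#' @return height x width integer matrix.
#' @export
to_grayscale <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3L] != 3L)
    stopf("'frame' must be a height x width x 3 RGB array")
  g <- 0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L]
  matrix(as.integer(round(g)), d[1L], d[2L])
}

# Row weights of area (block) averaging from src source pixels to dst
# target cells: W[i, j] is the fraction of target cell i's footprint
# covered by source pixel j.  Exact block means for integer ratios; for
# non-integer ratios each target cell averages its fractional footprint.
area_weights <- function(src, dst) {
  W <- matrix(0, dst, src)
  step <- src / dst
  for (i in seq_len(dst)) {
    lo <- (i - 1) * step
    hi <- i * step
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), src)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov / step
    }
  }
  W
}

#' Resize a grayscale frame and flatten to a pattern vector
#'
#' Downscales by area averaging (each target cell is the mean over its
#' source footprint, exact block means for integer factors) and flattens
#' row-major into the k = size*size pattern vector the subspace methods
#' operate on.  Values stay on the 0-255 scale; subsequent similarity
#' computations are scale-invariant, so no further normalization is done
#' here.
#'
#' @param gray height x width numeric matrix (single channel).
#' @param size target side length; default 8 gives the 64-dimensional
#'   pattern vector.
#' @return numeric vector of length `size^2`.
#' @export
resize_and_vectorize <- function(gray, size = 8L) {
  if (!is.matrix(gray) || nrow(gray) < 1L || ncol(gray) < 1L)
    stopf("'gray' must be a non-empty single-channel matrix")
  if (!is_count(size)) stopf("'size' must be a positive integer")
  Wr <- area_weights(nrow(gray), size)
  Wc <- area_weights(ncol(gray), size)
  out <- Wr %*% gray %*% t(Wc)
  as.vector(t(out))  # row-major
}

#' Drop frames marked as noise
#'
#' Removes frames flagged in a per-frame logical mask (e.g. takeoff/landing
#' frames belonging to neither class), preserving the order of the rest.
#' Marking is mask-driven -- from a manifest file or a manual list -- there
#' is no automatic noise detector.
#'
#' @param stream a [frame_stream()].
#' @param noise_mask logical vector, one entry per frame; `TRUE` drops.
#' @return the filtered [frame_stream()].
#' @export
remove_noise_frames <- function(stream, noise_mask) {
  if (!inherits(stream, "frame_stream")) stopf("'stream' must be a frame_stream")
  noise_mask <- as.logical(noise_mask)
  if (length(noise_mask) != length(stream$frames))
    stopf("'noise_mask' length (%d) must equal stream length (%d)",
          length(noise_mask), length(stream$frames))
  subset_stream(stream, !noise_mask)
}

#' Preprocess a frame stream to a pattern-vector matrix
#'
#' Runs every frame through the recognition preprocessing path (grayscale
#' conversion, area-average resize to `size` x `size`, row-major
#' vectorization) and stacks the results.
#'
#' @param stream a [frame_stream()].
#' @param size target side length (default 8).
#' @return numeric matrix, one row per frame, `size^2` columns; original
#'   frame indices as attribute `"indices"`.
#' @export
vectorize_stream <- function(stream, size = 8L) {
  if (!inherits(stream, "frame_stream")) stopf("'stream' must be a frame_stream")
  if (length(stream$frames) == 0L) stopf("empty stream")
  X <- t(vapply(stream$frames,
                function(f) resize_and_vectorize(to_grayscale(f), size),
                numeric(as.integer(size)^2)))
  attr(X, "indices") <- stream$indices
  X
}

#' Read/write a frame manifest
#'
#' The manifest is a plain CSV with columns `frame_index`, `label`,
#' `is_noise` recording per-frame ground truth for a frame directory.
#'
#' @param path CSV file path.
#' @return `read_manifest`: a data frame with those columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "label", "is_noise")
  if (!all(need %in% names(m)))
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  m$is_noise <- as.logical(m$is_noise)
  m
}

#' @rdname read_manifest
#' @param frame_index,label,is_noise per-frame columns to write.
#' @export
write_manifest <- function(path, frame_index, label,
                           is_noise = label == "noise") {
  utils::write.csv(data.frame(frame_index = frame_index, label = label,
                              is_noise = is_noise),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a frame stream as PNG files
#'
#' @param stream a [frame_stream()].
#' @param path output directory (created if absent); files are named
#'   `frame_000000.png` by original index so lexicographic order matches
#'   stream order.
#' @export
write_frame_dir <- function(stream, path) {
  if (!inherits(stream, "frame_stream")) stopf("'stream' must be a frame_stream")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stream$frames)) {
    f <- stream$frames[[i]] / 255
    png::writePNG(f, file.path(path, sprintf("frame_%06d.png",
                                             stream$indices[i])))
  }
  invisible(path)
}
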