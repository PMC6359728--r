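#' Save / load a fitted MSM model
#'
#' The on-disk format is a directory holding a JSON metadata file
#' (`model.json`: classes, counts, configuration, eigenvalues, dims,
#' centroids) and one plain CSV per category with the reference-subspace
#' basis (k rows, d columns, 17 significant digits -- full double
#' round-trip).  Text-only and portable; identical fits write
#' byte-identical files.
#'
#' @param model an [msm()] fit (training data is not persisted).
#' @param path directory to create/overwrite.
#' @return `write_msm`: `path`, invisibly.  `read_msm`: the restored
#'   `"msm"` object.
#' @export
write_msm <- function(model, path) {
  stopifnot(inherits(model, "msm"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "msmrec-model/1",
    classes = model$classes,
    counts = as.list(model$counts),
    k = model$k,
    config = model$config,
    subspaces = lapply(model$subspaces, function(S)
      list(dim = S$dim, eigenvalues = S$eigenvalues,
           all_eigenvalues = S$all_eigenvalues,
           contribution_rate = S$contribution_rate,
           centered = S$centered, center = S$center,
           n_samples = S$n_samples, clamped = S$clamped)))
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (nm in model$classes) {
    B <- model$subspaces[[nm]]$basis
    lines <- apply(B, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = ","))
    writeLines(lines, file.path(path, sprintf("basis_%s.csv", nm)))
  }
  invisible(path)
}

#' @rdname write_msm
#' @export
read_msm <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "msmrec-model/1"))
    stopf("'%s' is not an msmrec model directory", path)
  subspaces <- lapply(meta$classes, function(nm) {
    B <- do.call(rbind, lapply(
      strsplit(readLines(file.path(path, sprintf("basis_%s.csv", nm))), ","),
      as.numeric))
    m <- meta$subspaces[[nm]]
    structure(list(basis = B, eigenvalues = m$eigenvalues,
                   all_eigenvalues = m$all_eigenvalues,
                   dim = as.integer(m$dim), k = as.integer(meta$k),
                   contribution_rate = m$contribution_rate,
                   centered = isTRUE(m$centered),
                   center = if (is.null(m$center)) NULL
                            else as.numeric(m$center),
                   n_samples = as.integer(m$n_samples),
                   clamped = isTRUE(m$clamped)),
              class = "subspace")
  })
  names(subspaces) <- meta$classes
  cfg <- meta$config
  structure(list(classes = meta$classes, subspaces = subspaces,
                 counts = stats::setNames(as.integer(unlist(meta$counts)),
                                          names(meta$counts)),
                 k = as.integer(meta$k),
                 config = list(dim = cfg$dim, tau = cfg$tau,
                               centered = isTRUE(cfg$centered),
                               size = as.integer(cfg$size)),
                 data = NULL, call = NULL),
            class = "msm")
}
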