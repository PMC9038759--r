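# TIFF-backed stack and image I/O.
#
# Float32 files carry raw sample values (written by the package's own
# float TIFF writer, read back through tiff::readTIFF), so integer
# counts below 2^24 survive the round trip exactly. 16-bit files are
# stored as value/65535 and are exact for integers up to 65535.

sidecar_path <- function(path) paste0(path, ".yml")

#' Write a phase-stepping stack to disk
#'
#' @param stack a `stepping_stack`.
#' @param path output path. For the multi-page dialect this is a single
#'   `.tif` file; for the frame-sequence dialect it is a stem: frames are
#'   written as `<stem>_f01.tif`, `<stem>_f02.tif`, ...
#' @param dialect `"multipage"` (one multi-page TIFF) or `"sequence"`
#'   (one file per frame).
#' @param dtype `"float32"` or `"uint16"` (requires integer counts up to
#'   65535).
#' @return `path`, invisibly. A YAML sidecar `<path>.yml` carries the
#'   metadata (M, role, step indices, dtype, scale) needed to restore
#'   the stack.
#' @export
write_stack <- function(stack, path, dialect = c("multipage", "sequence"),
                        dtype = c("float32", "uint16")) {
  stopifnot(inherits(stack, "stepping_stack"))
  dialect <- match.arg(dialect)
  dtype <- match.arg(dtype)
  fr <- stack$frames
  if (dtype == "uint16") {
    if (max(fr) > 65535 || any(fr != round(fr)))
      stop("uint16 requires integer counts in [0, 65535]")
    scale <- 65535
  } else {
    scale <- 1  # float32 samples carry the raw counts directly
  }
  pages <- lapply(seq_len(dim(fr)[3]), function(i) fr[, , i] / scale)
  put <- function(pgs, where) {
    if (dtype == "uint16") {
      tiff::writeTIFF(pgs, where, bits.per.sample = 16L)
    } else {
      write_float_tiff(pgs, where)
    }
  }
  files <- if (dialect == "multipage") {
    put(pages, path)
    basename(path)
  } else {
    stems <- sprintf("%s_f%02d.tif", path, seq_along(pages))
    for (i in seq_along(pages)) put(pages[[i]], stems[i])
    basename(stems)
  }
  meta <- list(format = "gipret-stack", version = 1L,
               dialect = dialect, dtype = dtype, scale = scale,
               M = stack$M, role = stack$role,
               step_indices = as.integer(stack$step_indices),
               n_frames = dim(fr)[3], height = dim(fr)[1],
               width = dim(fr)[2], files = as.list(files))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a phase-stepping stack written by [write_stack()]
#'
#' @param path the path (or stem) that was given to [write_stack()].
#' @return a `stepping_stack`. Values equal the written ones: integer
#'   counts are restored exactly.
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar file '", sc, "' describing the stack at '",
         path, "'")
  meta <- yaml::read_yaml(sc)
  if (!identical(meta$format, "gipret-stack"))
    stop("'", sc, "' is not a stack sidecar")
  pages <- if (meta$dialect == "multipage") {
    tiff::readTIFF(path, all = TRUE)
  } else {
    lapply(file.path(dirname(path), unlist(meta$files)), tiff::readTIFF)
  }
  if (length(pages) != meta$n_frames)
    stop("frame count mismatch: sidecar announces ", meta$n_frames,
         " frame(s) but the image data holds ", length(pages))
  fr <- array(0, c(meta$height, meta$width, meta$n_frames))
  for (i in seq_along(pages)) fr[, , i] <- pages[[i]] * meta$scale
  if (identical(meta$dtype, "uint16")) fr <- round(fr)
  stepping_stack(fr, step_indices = unlist(meta$step_indices),
                 M = meta$M, role = meta$role)
}

#' Write a single image as 32-bit float TIFF with a metadata sidecar
#'
#' Samples are stored as IEEE float32, so any real-valued image (signed,
#' unnormalised) round trips to within float32 precision and
#' integer-valued data below 2^24 round trip exactly.
#'
#' @param img numeric matrix.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as.matrix(img)
  if (!all(is.finite(img))) stop("image contains non-finite values")
  write_float_tiff(img, path)
  yaml::write_yaml(list(format = "gipret-image", version = 1L,
                        offset = 0, scale = 1),
                   sidecar_path(path))
  invisible(path)
}

#' Read an image written by [write_image()]
#' @param path the `.tif` path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar file '", sc, "'")
  meta <- yaml::read_yaml(sc)
  tiff::readTIFF(path) * meta$scale + meta$offset
}

#' Export an image as 8-bit PNG for visualisation
#'
#' Applies a display window (clipping outside it) and writes an 8-bit
#' grey PNG. This is a lossy export intended for inspection only; stored
#' analysis data always go through [write_image()] unchanged, so metrics
#' never depend on the chosen display window.
#'
#' @param img numeric matrix.
#' @param path output `.png` path.
#' @param window length-2 display window (default the image range).
#' @return `path`, invisibly.
#' @export
export_png <- function(img, path, window = range(img)) {
  img <- (as.matrix(img) - window[1]) / max(window[2] - window[1], 1e-12)
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}
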