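# Volume I/O. The on-disk format is multi-page grayscale TIFF: one page per
# slow-scan position y, page rows = depth z, page columns = lateral x (the
# b-scan display convention). uint8 volumes round-trip bit-for-bit; float
# volumes are stored as 32-bit float samples.

#' Volume metadata record
#'
#' Pixel pitches and modality travel alongside a volume file; the TIFF
#' container itself stores only the pages.
#'
#' @param dx,dy,dz pixel pitches in micrometres
#' @param modality acquisition modality (see [pam_volume()])
#' @param value_scale `"float_unit"` or `"uint8"`
#' @return a named list usable as the `meta` argument of [read_volume()]
#' @export
volume_meta <- function(dx, dy, dz, modality,
                        value_scale = c("float_unit", "uint8")) {
  value_scale <- match.arg(value_scale)
  if (any(c(dx, dy, dz) <= 0))
    pam_stop("validation", "pixel pitches must be positive")
  list(dx = dx, dy = dy, dz = dz,
       modality = match.arg(modality, PAM_MODALITIES),
       value_scale = value_scale)
}

#' Write a PAM volume to disk
#'
#' @param vol a [pam_volume()]
#' @param path output file path (parent directory must exist)
#' @param format on-disk format; multi-page TIFF
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path, format = "tiff_stack") {
  stopifnot(inherits(vol, "pam_volume"))
  format <- match.arg(format, "tiff_stack")
  if (!dir.exists(dirname(path)))
    pam_stop("io", sprintf("parent directory does not exist: %s",
                           dirname(path)))
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(y) t(bscan_slice(vol, y)))  # z x x
  if (vol$value_scale == "uint8") {
    pages <- lapply(pages, function(p) p / 255)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
              silent = TRUE)
  } else {
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L),
              silent = TRUE)
  }
  if (inherits(ok, "try-error"))
    pam_stop("io", sprintf("failed to write TIFF: %s", path))
  invisible(path)
}

#' Read a PAM volume from disk
#'
#' Page `k` maps to slow-scan index `y = k`; within a page, rows are depth
#' `z` and columns are lateral `x`.
#'
#' @param path file path
#' @param meta a [volume_meta()] record (pitches, modality, value scale)
#' @param format on-disk format; multi-page TIFF
#' @return a [pam_volume()]
#' @export
read_volume <- function(path, meta, format = "tiff_stack") {
  format <- match.arg(format, "tiff_stack")
  if (!file.exists(path))
    pam_stop("io", sprintf("file does not exist: %s", path))
  pages <- try(tiff::readTIFF(path, all = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    pam_stop("format", sprintf("unreadable TIFF file: %s", path))
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    pam_stop("shape", "inconsistent page shapes in TIFF stack")
  n_y <- length(pages); n_z <- shp[1]; n_x <- shp[2]
  vol <- array(0, c(n_y, n_x, n_z))
  for (y in seq_len(n_y)) vol[y, , ] <- t(pages[[y]])
  if (meta$value_scale == "uint8") vol <- round(vol * 255)
  pam_volume(vol, dx = meta$dx, dy = meta$dy, dz = meta$dz,
             modality = meta$modality, value_scale = meta$value_scale)
}

#' Export a MAP (or depth-encoded MAP) as PNG
#'
#' @param map a `map_image` from [max_amplitude_projection()], or an RGB
#'   array from [depth_encoded_map()]
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
write_map_png <- function(map, path) {
  img <- if (inherits(map, "map_image")) {
    a <- map$amplitude
    if (max(a) > 0) a <- a / max(a)
    a
  } else map
  png::writePNG(clamp01(img), path)
  invisible(path)
}
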