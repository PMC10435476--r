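# PamVolume: the 3D amplitude container every pipeline stage consumes.
# Axis order is fixed as (y slow scan, x fast/lateral scan, z depth); a
# b-scan is the (x, z) plane at one y. One canonical order prevents silent
# transposes between the simulator, the networks and the metrics.

PAM_MODALITIES <- c("AR", "OR", "DEEP_AR", "GENERATED", "TRUTH")

#' Create a PAM amplitude volume
#'
#' A `pam_volume` holds a 3D non-negative amplitude array indexed
#' `(y, x, z)` — slow scan, lateral fast scan, depth — together with its
#' physical pixel pitches in micrometres and the acquisition modality.
#'
#' @param data 3D numeric array `(n_y, n_x, n_z)`, finite and non-negative.
#'   Values must lie in `[0, 1]` for `value_scale = "float_unit"` or
#'   `[0, 255]` (integers) for `"uint8"`.
#' @param dx,dy lateral pixel pitches in micrometres (fast and slow axes)
#' @param dz depth pixel pitch in micrometres
#' @param modality one of `"AR"`, `"OR"`, `"DEEP_AR"`, `"GENERATED"`,
#'   `"TRUTH"`
#' @param value_scale `"float_unit"` or `"uint8"`
#' @return an object of class `pam_volume`
#' @examples
#' v <- pam_volume(array(runif(4 * 8 * 16), c(4, 8, 16)), dx = 10, dy = 10,
#'                 dz = 20, modality = "TRUTH")
#' dim(v$data)
#' @export
pam_volume <- function(data, dx, dy, dz, modality,
                       value_scale = c("float_unit", "uint8")) {
  value_scale <- match.arg(value_scale)
  modality <- match.arg(modality, PAM_MODALITIES)
  if (!is.array(data) || length(dim(data)) != 3L)
    pam_stop("validation", "`data` must be a 3D array (y, x, z)")
  if (any(dim(data) == 0L))
    pam_stop("validation", "empty volume: every dimension must be positive")
  if (!all(is.finite(data)) || any(data < 0))
    pam_stop("validation", "volume values must be finite and non-negative")
  hi <- if (value_scale == "float_unit") 1 else 255
  if (max(data) > hi)
    pam_stop("validation",
             sprintf("values exceed %s bound (%g)", value_scale, hi))
  for (nm in c("dx", "dy", "dz"))
    assert_scalar_pos(get(nm), nm)
  structure(
    list(data = data, dx = dx, dy = dy, dz = dz, modality = modality,
         value_scale = value_scale),
    class = "pam_volume")
}

#' @export
print.pam_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<pam_volume> %s  %d x %d x %d (y,x,z)  pitch %g/%g/%g um  [%s]\n",
    x$modality, d[1], d[2], d[3], x$dy, x$dx, x$dz, x$value_scale))
  cat(sprintf("  amplitude range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.pam_volume <- function(x) dim(x$data)

# b-scan at slow-scan index y as an (n_x, n_z) matrix
bscan_slice <- function(vol, y) {
  matrix(vol$data[y, , ], nrow = dim(vol$data)[2], ncol = dim(vol$data)[3])
}

#' Maximum amplitude projection
#'
#' Projects a volume along depth: for every lateral position `(y, x)` the
#' amplitude is the maximum over `z` and `depth_index` records the depth
#' sample (0-based) attaining it. Depth ties resolve to the shallowest
#' sample, which is deterministic and physically conservative.
#'
#' @param vol a [pam_volume()]
#' @return a `map_image`: list with `amplitude` and `depth_index` matrices
#'   `(n_y, n_x)` plus pitches and the source depth count `n_z`
#' @export
max_amplitude_projection <- function(vol) {
  stopifnot(inherits(vol, "pam_volume"))
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = d[1] * d[2], ncol = d[3])
  idx <- max.col(m, ties.method = "first")      # first = shallowest z
  amp <- m[cbind(seq_len(nrow(m)), idx)]
  structure(
    list(amplitude = matrix(amp, d[1], d[2]),
         depth_index = matrix(idx - 1L, d[1], d[2]),
         n_z = d[3], dx = vol$dx, dy = vol$dy, dz = vol$dz,
         modality = vol$modality),
    class = "map_image")
}

#' @export
print.map_image <- function(x, ...) {
  cat(sprintf("<map_image> %d x %d (y,x), from %d depth samples [%s]\n",
              nrow(x$amplitude), ncol(x$amplitude), x$n_z, x$modality))
  invisible(x)
}

#' Depth-encoded maximum amplitude projection
#'
#' Renders a MAP as RGB: hue encodes the binned depth of the per-column
#' maximum, brightness encodes the amplitude. Deterministic for a fixed
#' input.
#'
#' @param vol a [pam_volume()]
#' @param colormap_bins number of depth hue bins (>= 2)
#' @return numeric array `(n_y, n_x, 3)` of RGB values in `[0, 1]`
#' @export
depth_encoded_map <- function(vol, colormap_bins = 64L) {
  if (colormap_bins < 2) pam_stop("validation", "colormap_bins must be >= 2")
  m <- max_amplitude_projection(vol)
  bins <- pmin(colormap_bins - 1L,
               floor(m$depth_index / m$n_z * colormap_bins))
  # blue (shallow) -> red (deep) sweep over 240..0 degrees
  hues <- seq(2 / 3, 0, length.out = colormap_bins)
  amp <- m$amplitude / max(m$amplitude, 1e-12)
  if (max(m$amplitude) == 0) amp <- m$amplitude
  col <- grDevices::hsv(hues[bins + 1L], s = 1, v = 1)
  rgb <- grDevices::col2rgb(col) / 255
  out <- array(0, c(nrow(amp), ncol(amp), 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(rgb[ch, ], nrow(amp), ncol(amp)) * amp
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a maximum amplitude projection
#'
#' @param object a `map_image`
#' @param what `"amplitude"` or `"depth"`
#' @param ... unused
#' @return a ggplot
#' @method autoplot map_image
#' @export
autoplot.map_image <- function(object, what = c("amplitude", "depth"), ...) {
  what <- match.arg(what)
  val <- if (what == "amplitude") object$amplitude else
    object$depth_index * object$dz
  df <- tibble(
    x_um = rep((seq_len(ncol(val)) - 1) * object$dx, each = nrow(val)),
    y_um = rep((seq_len(nrow(val)) - 1) * object$dy, times = ncol(val)),
    value = as.vector(val))
  lab <- if (what == "amplitude") "amplitude" else "depth (um)"
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("MAP [%s]", object$modality))
}
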