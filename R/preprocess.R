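# Preprocessing chain: whole-volume normalization, per-A-line bandpass +
# envelope detection, deterministic patch tiling (random jitter disabled so
# repeated runs tile identically), 8-bit conversion, and paired/unpaired
# dataset assembly.

#' Normalize a volume by its global maximum
#'
#' Amplitudes are normalized over the entire volume (not per b-scan) so that
#' relative amplitudes between slices are preserved — normalizing per slice
#' would erase the depth-sensitivity differences the enhancement is supposed
#' to learn.
#'
#' @param vol a [pam_volume()] with at least one nonzero voxel
#' @return a float-unit [pam_volume()] with maximum exactly 1
#' @export
normalize_volume <- function(vol) {
  stopifnot(inherits(vol, "pam_volume"))
  m <- max(vol$data)
  if (m == 0)
    pam_stop("normalization", "cannot normalize an all-zero volume")
  pam_volume(vol$data / m, dx = vol$dx, dy = vol$dy, dz = vol$dz,
             modality = vol$modality, value_scale = "float_unit")
}

#' Transducer passband specification
#'
#' Defaults follow a +/-80% fractional bandwidth around the transducer
#' centre frequency: 10–90 MHz for the 50 MHz dual-system transducer,
#' 1–9 MHz for the 5 MHz deep transducer.
#'
#' @param low_mhz,high_mhz passband edges in MHz
#' @param sample_rate_mhz A-line sampling rate in MHz
#' @param order Butterworth filter order
#' @return a `band_spec` list
#' @export
band_spec <- function(low_mhz, high_mhz, sample_rate_mhz, order = 4L) {
  if (!(0 < low_mhz && low_mhz < high_mhz &&
        high_mhz < sample_rate_mhz / 2))
    pam_stop("validation",
             "need 0 < low < high < sample_rate/2 (MHz)")
  structure(list(low_mhz = low_mhz, high_mhz = high_mhz,
                 sample_rate_mhz = sample_rate_mhz, order = as.integer(order)),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
band_spec_50mhz <- function(sample_rate_mhz = 250)
  band_spec(10, 90, sample_rate_mhz)

#' @rdname band_spec
#' @export
band_spec_5mhz <- function(sample_rate_mhz = 50)
  band_spec(1, 9, sample_rate_mhz)

# analytic-signal magnitude via the frequency-domain Hilbert construction
envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Bandpass-filter A-lines and take the signal envelope
#'
#' Applies a zero-phase (forward-backward Butterworth) bandpass to each
#' A-line, then the analytic-signal magnitude. Zero-phase filtering avoids
#' depth-axis shifts that would break AR/OR pairing.
#'
#' @param alines numeric vector (one A-line) or matrix with one A-line per
#'   column (depth along rows)
#' @param band a [band_spec()]
#' @return non-negative envelope signals, same shape as the input
#' @export
bandpass_envelope <- function(alines, band) {
  stopifnot(inherits(band, "band_spec"))
  vec_in <- is.null(dim(alines))
  x <- if (vec_in) matrix(alines, ncol = 1) else alines
  if (nrow(x) <= 3 * band$order)
    pam_stop("validation", "A-lines shorter than 3x filter order")
  nyq <- band$sample_rate_mhz / 2
  bf <- signal::butter(band$order,
                       c(band$low_mhz, band$high_mhz) / nyq, type = "pass")
  out <- apply(x, 2, function(col) {
    envelope(as.numeric(signal::filtfilt(bf, col)))
  })
  out <- matrix(out, nrow = nrow(x))
  if (vec_in) as.numeric(out) else out
}

# 0-based patch start offsets covering [0, n) with the final patch shifted
# inward so it ends exactly at the border (no zero-padding on real data)
patch_starts <- function(n, size, stride) {
  if (size <= 0) pam_stop("validation", "patch_size must be positive")
  if (n < size) pam_stop("validation", "dimension smaller than patch_size")
  s <- seq(0L, n - size, by = stride)
  if (s[length(s)] != n - size) s <- c(s, n - size)
  as.integer(s)
}

#' Tile a b-scan into fixed-size patches
#'
#' Deterministic raster-order tiling with no random jitter: calling twice on
#' the same b-scan yields identical patch sets. Edge patches are shifted
#' inward so every patch contains real data and coverage is complete.
#' B-scans smaller than `patch_size` are zero-padded at the bottom/right
#' edge first.
#'
#' @param bscan 2D matrix `(n_x, n_z)`
#' @param patch_size square patch side in pixels (default 256)
#' @param stride tiling stride in pixels (default `patch_size`,
#'   i.e. non-overlapping)
#' @param source_index slow-scan index the b-scan came from (bookkeeping)
#' @return a `patch_set`: `patches` array `(patch_size, patch_size, n)`,
#'   an `origins` tibble with 0-based `(x0, z0)`, and the tiling geometry
#' @export
extract_patches <- function(bscan, patch_size = 256L, stride = patch_size,
                            source_index = 1L) {
  if (patch_size <= 0) pam_stop("validation", "patch_size must be positive")
  if (stride <= 0) pam_stop("validation", "stride must be positive")
  bscan <- as.matrix(bscan)
  src_shape <- dim(bscan)
  if (any(src_shape < patch_size)) {
    padded <- matrix(0, max(src_shape[1], patch_size),
                     max(src_shape[2], patch_size))
    padded[seq_len(src_shape[1]), seq_len(src_shape[2])] <- bscan
    bscan <- padded
  }
  xs <- patch_starts(nrow(bscan), patch_size, stride)
  zs <- patch_starts(ncol(bscan), patch_size, stride)
  origins <- tibble(
    patch = seq_len(length(xs) * length(zs)),
    x0 = rep(xs, times = length(zs)),
    z0 = rep(zs, each = length(xs)),
    source_index = as.integer(source_index))
  patches <- array(0, c(patch_size, patch_size, nrow(origins)))
  for (i in seq_len(nrow(origins))) {
    patches[, , i] <- bscan[origins$x0[i] + seq_len(patch_size),
                            origins$z0[i] + seq_len(patch_size)]
  }
  structure(
    list(patches = patches, origins = origins, source_shape = src_shape,
         patch_size = as.integer(patch_size), stride = as.integer(stride)),
    class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %dx%d, stride %d, source %dx%d\n",
              dim(x$patches)[3], x$patch_size, x$patch_size, x$stride,
              x$source_shape[1], x$source_shape[2]))
  invisible(x)
}

#' Convert unit-scaled values to unsigned 8-bit
#'
#' Uses round-half-up (`floor(v*255 + 0.5)`) so conversions are bit-exact
#' across implementations.
#'
#' @param x numeric array/matrix with values in `[0, 1]`, or a float-unit
#'   [pam_volume()]
#' @return same shape with integer values in `0..255` (a uint8
#'   `pam_volume` when the input was a volume)
#' @export
to_uint8 <- function(x) {
  if (inherits(x, "pam_volume")) {
    if (x$value_scale != "float_unit")
      pam_stop("validation", "volume is already uint8")
    return(pam_volume(to_uint8(x$data), dx = x$dx, dy = x$dy, dz = x$dz,
                      modality = x$modality, value_scale = "uint8"))
  }
  if (any(x < 0 | x > 1))
    pam_stop("validation", "values outside [0, 1]")
  floor(x * 255 + 0.5)
}

#' Assemble an aligned paired dataset from co-registered AR and OR volumes
#'
#' Every AR patch is paired with the OR patch from the identical origin and
#' slow-scan index (one-to-one labeling); pair count is
#' `n_slices * patches_per_slice`.
#'
#' @param ar_vol,or_vol co-registered [pam_volume()]s with identical shapes
#'   and pitches
#' @param patch_size,stride tiling parameters (see [extract_patches()])
#' @return a `paired_dataset`: arrays `A` and `O` of shape
#'   `(patch_size, patch_size, n_pairs)` plus an `index` tibble of origins
#' @export
build_paired <- function(ar_vol, or_vol, patch_size = 256L,
                         stride = patch_size) {
  stopifnot(inherits(ar_vol, "pam_volume"), inherits(or_vol, "pam_volume"))
  if (!identical(dim(ar_vol$data), dim(or_vol$data)) ||
      ar_vol$dx != or_vol$dx || ar_vol$dz != or_vol$dz)
    pam_stop("registration",
             "AR and OR volumes must be co-registered (same shape, pitches)")
  n_y <- dim(ar_vol$data)[1]
  a_sets <- lapply(seq_len(n_y), function(y)
    extract_patches(bscan_slice(ar_vol, y), patch_size, stride, y))
  o_sets <- lapply(seq_len(n_y), function(y)
    extract_patches(bscan_slice(or_vol, y), patch_size, stride, y))
  A <- array(unlist(lapply(a_sets, `[[`, "patches")),
             c(patch_size, patch_size,
               sum(vapply(a_sets, function(s) dim(s$patches)[3], 1))))
  O <- array(unlist(lapply(o_sets, `[[`, "patches")), dim(A))
  index <- dplyr::bind_rows(lapply(a_sets, `[[`, "origins"))
  index$pair <- seq_len(nrow(index))
  structure(list(A = A, O = O, index = as_tibble(index),
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d aligned (AR, OR) patch pairs of %dx%d\n",
              dim(x$A)[3], x$patch_size, x$patch_size))
  invisible(x)
}

#' Assemble decoupled unpaired patch pools (label-free training)
#'
#' The two pools are tiled independently and shuffled with a seeded
#' permutation, deliberately destroying any alignment between the domains.
#'
#' @inheritParams build_paired
#' @param seed integer seed for the pool shuffles
#' @return an `unpaired_dataset` with independent pools `A` and `O`
#' @export
build_unpaired <- function(ar_vol, or_vol, patch_size = 256L,
                           stride = patch_size, seed = 0L) {
  pool <- function(vol, tag) {
    n_y <- dim(vol$data)[1]
    sets <- lapply(seq_len(n_y), function(y)
      extract_patches(bscan_slice(vol, y), patch_size, stride, y))
    n <- sum(vapply(sets, function(s) dim(s$patches)[3], 1))
    arr <- array(unlist(lapply(sets, `[[`, "patches")),
                 c(patch_size, patch_size, n))
    set.seed(derive_seed(seed, paste0("unpaired_", tag)))
    arr[, , sample.int(n), drop = FALSE]
  }
  structure(list(A = pool(ar_vol, "A"), O = pool(or_vol, "O"),
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "unpaired_dataset")
}

#' @export
print.unpaired_dataset <- function(x, ...) {
  cat(sprintf("<unpaired_dataset> pools: %d AR, %d OR patches of %dx%d\n",
              dim(x$A)[3], dim(x$O)[3], x$patch_size, x$patch_size))
  invisible(x)
}
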