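# Whole-volume inference: tile each b-scan, translate every patch with the
# trained generator, and stitch the translated patches back with
# overlap-aware blending. Default inference stride is patch_size/2 with
# average blending, which suppresses patch-seam artifacts; training tiles
# are non-overlapping. No post-hoc thresholding or bandpass is applied
# after generation.

#' Reassemble patches into a b-scan
#'
#' `blend = "average"` takes the arithmetic mean of all patches covering a
#' pixel; `"feathered"` weights each patch by a separable triangular window
#' so seams fade out smoothly.
#'
#' @param patch_set a `patch_set` (possibly with modified patch pixels)
#' @param blend `"average"` or `"feathered"`
#' @param target_shape output `(n_x, n_z)`; defaults to the source shape
#'   recorded in the patch set
#' @return 2D matrix of the stitched b-scan
#' @export
stitch_patches <- function(patch_set, blend = c("average", "feathered"),
                           target_shape = NULL) {
  blend <- match.arg(blend)
  stopifnot(inherits(patch_set, "patch_set"))
  ps <- patch_set$patch_size
  shape <- target_shape %||% pmax(patch_set$source_shape, ps)
  acc <- matrix(0, max(shape[1], ps), max(shape[2], ps))
  wgt <- matrix(0, nrow(acc), ncol(acc))
  w <- if (blend == "average") matrix(1, ps, ps) else {
    tri <- 1 - abs(seq(-1, 1, length.out = ps + 2)[2:(ps + 1)])
    outer(tri, tri)
  }
  for (i in seq_len(nrow(patch_set$origins))) {
    xi <- patch_set$origins$x0[i] + seq_len(ps)
    zi <- patch_set$origins$z0[i] + seq_len(ps)
    if (max(xi) > nrow(acc) || max(zi) > ncol(acc))
      pam_stop("plan", "patch origin outside the stitch target")
    acc[xi, zi] <- acc[xi, zi] + patch_set$patches[, , i] * w
    wgt[xi, zi] <- wgt[xi, zi] + w
  }
  out <- acc / pmax(wgt, .Machine$double.eps)
  out[seq_len(shape[1]), seq_len(shape[2]), drop = FALSE]
}

#' Enhance a single b-scan with a trained generator
#'
#' Tiles the b-scan (inward-shifted edge tiles, no jitter), maps every
#' patch through the generator, and stitches the results. Output has the
#' same shape as the input with values in `[0, 1]`.
#'
#' @param bscan 2D matrix `(n_x, n_z)` in `[0, 1]`
#' @param model a `pam_gan` (its forward generator is used)
#' @param patch_size tile side; must be divisible by the generator's
#'   downsampling factor
#' @param stride tiling stride; default `patch_size / 2` (overlapping)
#' @param blend stitching blend mode
#' @return enhanced 2D matrix, same shape as `bscan`
#' @export
enhance_bscan <- function(bscan, model, patch_size = 256L,
                          stride = max(1L, patch_size %/% 2L),
                          blend = "average") {
  stopifnot(inherits(model, "pam_gan"))
  bscan <- as.matrix(bscan)
  set <- extract_patches(bscan, patch_size, stride)
  for (i in seq_len(dim(set$patches)[3]))
    set$patches[, , i] <- gan_generate(model$generator, set$patches[, , i])
  out <- stitch_patches(set, blend = blend)
  clamp01(out[seq_len(nrow(bscan)), seq_len(ncol(bscan)), drop = FALSE])
}

#' Enhance a whole volume slice by slice
#'
#' Applies [enhance_bscan()] independently to every slow-scan slice (the
#' generator has no cross-slice state), copies the metadata and tags the
#' result `GENERATED`.
#'
#' @inheritParams enhance_bscan
#' @param vol a float-unit [pam_volume()]
#' @return a `GENERATED` [pam_volume()] of identical shape
#' @export
enhance_volume <- function(vol, model, patch_size = 256L,
                           stride = max(1L, patch_size %/% 2L),
                           blend = "average") {
  stopifnot(inherits(vol, "pam_volume"))
  d <- dim(vol$data)
  out <- array(0, d)
  for (y in seq_len(d[1]))
    out[y, , ] <- enhance_bscan(bscan_slice(vol, y), model, patch_size,
                                stride, blend)
  pam_volume(out, dx = vol$dx, dy = vol$dy, dz = vol$dz,
             modality = "GENERATED", value_scale = "float_unit")
}
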