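# Quality-comparison suite: SNR and CNR in dB over explicit rectangular
# ROIs, windowed SSIM, physical line profiles and Gaussian-fit FWHM.
# ROI selection is explicit caller input and is recorded in reports; there
# is no automatic ROI guessing.

#' Rectangular region of interest (0-based, half-open bounds)
#'
#' @param row0,row1 half-open row bounds: rows `row0 .. row1-1`
#' @param col0,col1 half-open column bounds
#' @param role `"signal"` or `"background"` (bookkeeping)
#' @return an `roi`
#' @export
roi <- function(row0, row1, col0, col1, role = c("signal", "background")) {
  role <- match.arg(role)
  if (row1 <= row0 || col1 <= col0)
    pam_stop("validation", "ROI must be non-empty (half-open bounds)")
  if (min(row0, col0) < 0)
    pam_stop("validation", "ROI bounds must be non-negative")
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1),
                 role = role),
            class = "roi")
}

roi_pixels <- function(img, r) {
  if (r$row1 > nrow(img) || r$col1 > ncol(img))
    pam_stop("validation", "ROI exceeds image bounds")
  img[(r$row0 + 1):r$row1, (r$col0 + 1):r$col1]
}

roi_label <- function(r) sprintf("[%d,%d)x[%d,%d)", r$row0, r$row1,
                                 r$col0, r$col1)

#' Signal-to-noise ratio in decibels
#'
#' `SNR = 10 log10(P_signal / P_noise)` with `P` the mean squared amplitude
#' over the ROI.
#'
#' @param img 2D image matrix
#' @param signal,noise [roi()]s for the signal and noise regions
#' @return SNR in dB
#' @export
snr_db <- function(img, signal, noise) {
  p_sig <- mean(roi_pixels(img, signal)^2)
  p_noi <- mean(roi_pixels(img, noise)^2)
  if (p_noi <= 0)
    pam_stop("undefined_metric", "noise power is zero in the noise ROI")
  10 * log10(p_sig / p_noi)
}

#' Contrast-to-noise ratio in decibels
#'
#' `CNR = 10 log10((mu_signal - mu_background) / sigma_background)`, taken
#' exactly as printed (a 10-, not 20-, log of the amplitude ratio).
#'
#' @param img 2D image matrix
#' @param signal,background [roi()]s
#' @return CNR in dB
#' @export
cnr_db <- function(img, signal, background) {
  mu_s <- mean(roi_pixels(img, signal))
  bg <- roi_pixels(img, background)
  s_b <- sd(as.numeric(bg))
  if (!is.finite(s_b) || s_b == 0)
    pam_stop("undefined_metric", "background standard deviation is zero")
  if (mu_s <= mean(bg))
    pam_stop("undefined_metric",
             "signal mean does not exceed background mean; unusable ROIs")
  10 * log10((mu_s - mean(bg)) / s_b)
}

#' Structural similarity index
#'
#' Mean over sliding windows of the luminance x contrast x structure
#' product with the standard stabilizing constants `C1 = (K1 L)^2`,
#' `C2 = (K2 L)^2`. Uniform square window, sample (n-1) covariance.
#' Symmetric in its two arguments; `ssim(x, x) = 1`.
#'
#' @param a,b equal-shape 2D matrices
#' @param window odd window side, at most the smaller image dimension
#' @param k1,k2 stabilizer fractions
#' @param data_range dynamic range `L` (1 for unit-scaled, 255 for uint8)
#' @return similarity in `[-1, 1]`
#' @export
ssim <- function(a, b, window = 7L, k1 = 0.01, k2 = 0.03, data_range = 1) {
  if (!identical(dim(a), dim(b)))
    pam_stop("validation", "images must have identical shapes")
  if (window %% 2 == 0 || window > min(dim(a)))
    pam_stop("validation", "window must be odd and fit inside the image")
  n <- window^2
  wa <- cpp_windows(a, window)
  wb <- cpp_windows(b, window)
  mua <- rowMeans(wa); mub <- rowMeans(wb)
  va <- (rowSums(wa^2) - n * mua^2) / (n - 1)
  vb <- (rowSums(wb^2) - n * mub^2) / (n - 1)
  cab <- (rowSums(wa * wb) - n * mua * mub) / (n - 1)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  s <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
    ((mua^2 + mub^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Complex-wavelet structural similarity (optional metric)
#'
#' A single-scale complex Gabor-band comparison: both images are filtered
#' with a small bank of oriented complex Gabor kernels and the standard
#' CW-SSIM statistic is averaged over bands and positions. Provided as an
#' optional robustness metric; parameter choices are a repository
#' convention.
#'
#' @param a,b equal-shape 2D matrices
#' @param wavelength carrier wavelength in pixels
#' @param n_orientations number of orientation bands
#' @param k stabilizer
#' @return similarity in `[0, 1]`
#' @export
cw_ssim <- function(a, b, wavelength = 8, n_orientations = 4, k = 0.01) {
  if (!identical(dim(a), dim(b)))
    pam_stop("validation", "images must have identical shapes")
  ksz <- min(2L * floor(wavelength) + 1L, min(dim(a)) - 1L +
               (min(dim(a)) %% 2L == 0L))
  if (ksz %% 2 == 0) ksz <- ksz - 1L
  half <- (ksz - 1) / 2
  xs <- seq(-half, half)
  sim <- 0
  for (ori in seq_len(n_orientations)) {
    th <- pi * (ori - 1) / n_orientations
    u <- outer(xs * cos(th), xs * sin(th), `+`)
    env <- outer(dnorm(xs, sd = wavelength / 2),
                 dnorm(xs, sd = wavelength / 2))
    kern <- env * exp(2i * pi * u / wavelength)
    ca <- conv2_valid(a, kern)
    cb <- conv2_valid(b, kern)
    num <- 2 * abs(sum(ca * Conj(cb))) + k
    den <- sum(abs(ca)^2) + sum(abs(cb)^2) + k
    sim <- sim + num / den
  }
  sim / n_orientations
}

# direct valid-mode 2D complex convolution (small kernels only)
conv2_valid <- function(img, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  oh <- nrow(img) - kh + 1; ow <- ncol(img) - kw + 1
  w <- cpp_windows(img, kh)  # square kernels only
  stopifnot(kh == kw)
  matrix(w %*% as.vector(kern), oh, ow)
}

#' Extract a physical line profile from an image
#'
#' @param img 2D matrix; for a b-scan, rows are lateral x and columns are
#'   depth z
#' @param line 1-based row or column index
#' @param along `"row"` (profile varies along columns) or `"col"`
#' @param pitch_um physical pixel pitch along the profile, micrometres
#' @param axis `"lateral"` or `"axial"` label carried into the profile
#' @return a `profile`: tibble with `position_um` and `value`, plus the
#'   axis attribute
#' @export
extract_profile <- function(img, line, along = c("col", "row"),
                            pitch_um = 1,
                            axis = c("lateral", "axial")) {
  along <- match.arg(along); axis <- match.arg(axis)
  n_max <- if (along == "col") ncol(img) else nrow(img)
  if (line < 1 || line > n_max)
    pam_stop("validation", "profile line outside image bounds")
  values <- if (along == "col") img[, line] else img[line, ]
  out <- tibble(position_um = (seq_along(values) - 1) * pitch_um,
                value = as.numeric(values))
  structure(out, axis = axis, class = c("profile", class(out)))
}

#' Fit a Gaussian to a line profile and report its FWHM
#'
#' Least-squares fit of `amplitude * exp(-(x - center)^2 / (2 sigma^2)) +
#' offset` (Levenberg-Marquardt) with moment-based initialization.
#' `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param profile a `profile` from [extract_profile()], or any data frame
#'   with `position_um` and `value` columns
#' @return a `gaussian_fit`: amplitude, center, sigma, offset, FWHM (all in
#'   the profile's position units) and fit RMSE
#' @export
fit_gaussian <- function(profile) {
  x <- profile$position_um; y <- profile$value
  if (length(x) < 5)
    pam_stop("validation", "need at least 5 profile samples")
  if (max(y) - min(y) <= 0)
    pam_stop("fit", "constant profile: nothing to fit")
  # peak-based initialization: centre at the argmax, width from the
  # half-maximum crossings around it. Global moments would be polluted by
  # the noise floor of mostly-flat profiles and start the fit at a
  # degenerate flat solution.
  off0 <- stats::median(y)
  peak <- which.max(y)
  mu0 <- x[peak]
  amp0 <- y[peak] - off0
  above <- y > off0 + amp0 / 2
  lo <- peak; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- peak; while (hi < length(y) && above[hi + 1]) hi <- hi + 1
  px <- min(diff(x))
  sig0 <- max(px / 2, (x[hi] - x[lo] + px) / (2 * sqrt(2 * log(2))))
  residual <- function(p) {
    y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4])
  }
  fit <- try(minpack.lm::nls.lm(
    par = c(A = amp0, mu = mu0, s = sig0, c0 = off0), fn = residual,
    lower = c(0, min(x) - diff(range(x)), px / 10, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4))
    pam_stop("fit", sprintf(
      "Gaussian fit did not converge (init A=%.3g mu=%.3g s=%.3g c=%.3g)",
      amp0, mu0, sig0, off0))
  p <- fit$par
  sigma <- abs(unname(p[["s"]]))
  structure(
    list(amplitude = unname(p[["A"]]), center_um = unname(p[["mu"]]),
         sigma_um = sigma, offset = unname(p[["c0"]]),
         fwhm_um = fwhm_from_sigma(sigma),
         rmse = sqrt(mean(residual(p)^2)),
         n = length(x)),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<gaussian_fit> FWHM %.3g um (sigma %.3g, center %.3g, rmse %.3g)\n",
    x$fwhm_um, x$sigma_um, x$center_um, x$rmse))
  invisible(x)
}

#' @rdname fit_gaussian
#' @param x a `gaussian_fit`
#' @param ... unused
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, center_um = x$center_um,
         sigma_um = x$sigma_um, offset = x$offset, fwhm_um = x$fwhm_um,
         rmse = x$rmse, n = x$n)
}

#' Side-by-side quality report for a labeled set of images
#'
#' One row per labeled image with its SNR, CNR, SSIM against a reference
#' image, and Gaussian-fit FWHM along a profile line. The ROIs and profile
#' line used are recorded in the report columns.
#'
#' @param images named list of equal-shape 2D matrices (e.g. `AR`,
#'   `cGAN`, `CycleGAN`, `OR`)
#' @param signal,background [roi()]s used for SNR/CNR (background doubles
#'   as the noise ROI)
#' @param reference name of the reference image for SSIM (default the last
#'   image in the list)
#' @param profile_line optional 1-based line index for FWHM profiling
#' @param along,pitch_um,axis profile parameters (see [extract_profile()])
#' @return a `metrics_report` tibble
#' @export
compare_images <- function(images, signal, background,
                           reference = names(images)[length(images)],
                           profile_line = NULL, along = "col",
                           pitch_um = 1, axis = "lateral") {
  stopifnot(is.list(images), !is.null(names(images)))
  shp <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), shp), logical(1))))
    pam_stop("validation", "all images must share one shape")
  ref <- images[[reference]]
  rows <- lapply(names(images), function(nm) {
    img <- images[[nm]]
    fw <- NA_real_
    if (!is.null(profile_line)) {
      fw <- tryCatch(
        fit_gaussian(extract_profile(img, profile_line, along, pitch_um,
                                     axis))$fwhm_um,
        error = function(e) NA_real_)
    }
    tibble(image = nm,
           snr_db = snr_db(img, signal, background),
           cnr_db = tryCatch(cnr_db(img, signal, background),
                             error = function(e) NA_real_),
           ssim = ssim(img, ref),
           fwhm_um = fw,
           reference = reference,
           roi_signal = roi_label(signal),
           roi_background = roi_label(background))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Plot a quality report as grouped bars
#'
#' @param object a `metrics_report`
#' @param ... unused
#' @return a ggplot
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(image = object$image, metric = "SNR (dB)",
           value = object$snr_db),
    tibble(image = object$image, metric = "CNR (dB)",
           value = object$cnr_db),
    tibble(image = object$image, metric = "SSIM", value = object$ssim),
    tibble(image = object$image, metric = "FWHM (um)",
           value = object$fwhm_um))
  ggplot2::ggplot(df, ggplot2::aes(.data$image, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
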