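# Dual-PSF forward simulator. A known absorber geometry (tilted hairs or a
# random branching vessel tree) is scanned twice with different point spread
# functions — an AR-like one (coarse lateral focus, deep visibility) and an
# OR-like one (tight focus, shallow visibility) — producing intrinsically
# co-registered training pairs with ground truth.

#' Phantom geometry specification
#'
#' `kind = "hairs"` places straight hair-like cylinders whose centreline
#' depth increases linearly along the fast axis (a depth-staircase target
#' for visibility experiments); `kind = "vessels"` grows a seeded random
#' branching tube tree with smoothly varying direction and diameter.
#'
#' @param kind `"hairs"` or `"vessels"`
#' @param extent_um physical extent `(X, Y, Z)` in micrometres
#' @param n_hairs number of hairs
#' @param hair_diameter_um hair diameter in micrometres
#' @param hair_depth_range_um `(z_start, z_end)` of the linear tilt
#' @param n_seeds number of vessel tree roots
#' @param branch_prob per-step branching probability
#' @param diameter_range_um vessel diameter range `(min, max)`
#' @param tortuosity direction-perturbation scale per step (0 = straight)
#' @param absorption per-structure amplitude in `(0, 1]`
#' @return a `phantom_spec`
#' @export
phantom_spec <- function(kind = c("hairs", "vessels"),
                         extent_um = c(1280, 320, 2560),
                         n_hairs = 3L, hair_diameter_um = 150,
                         hair_depth_range_um = c(100, 2000),
                         n_seeds = 3L, branch_prob = 0.08,
                         diameter_range_um = c(40, 120), tortuosity = 0.25,
                         absorption = 1) {
  kind <- match.arg(kind)
  if (absorption <= 0 || absorption > 1)
    pam_stop("validation", "absorption must be in (0, 1]")
  if (any(extent_um <= 0))
    pam_stop("validation", "extent must be positive")
  if (kind == "hairs" &&
      (hair_depth_range_um[2] > extent_um[3] || hair_diameter_um <= 0 ||
       max(hair_depth_range_um) + hair_diameter_um / 2 > extent_um[3]))
    pam_stop("geometry", "hairs do not fit inside the phantom extent")
  structure(list(kind = kind, extent_um = extent_um, n_hairs = n_hairs,
                 hair_diameter_um = hair_diameter_um,
                 hair_depth_range_um = hair_depth_range_um,
                 n_seeds = n_seeds, branch_prob = branch_prob,
                 diameter_range_um = diameter_range_um,
                 tortuosity = tortuosity, absorption = absorption),
            class = "phantom_spec")
}

#' Point-spread-function model of a PAM system
#'
#' A separable Gaussian PSF: isotropic lateral 2D Gaussian whose FWHM grows
#' linearly outside the depth of focus, times an axial 1D Gaussian.
#' Amplitude decays as `exp(-z / attenuation_length_um)` and is hard-zeroed
#' beyond `max_visible_depth_um`.
#'
#' @param lateral_fwhm_focus_um lateral FWHM at focus, micrometres
#' @param axial_fwhm_um axial FWHM, micrometres
#' @param focal_depth_um focal depth, micrometres
#' @param depth_of_focus_um depth-of-focus span around the focal depth
#' @param out_of_focus_growth lateral FWHM multiplier per micrometre beyond
#'   the depth of focus
#' @param attenuation_length_um 1/e depth-decay constant, micrometres
#' @param max_visible_depth_um hard visibility cutoff, micrometres
#' @return a `psf_model`
#' @export
psf_model <- function(lateral_fwhm_focus_um, axial_fwhm_um,
                      focal_depth_um = 500, depth_of_focus_um = 400,
                      out_of_focus_growth = 0.005,
                      attenuation_length_um = 1500,
                      max_visible_depth_um = 1900) {
  vals <- c(lateral_fwhm_focus_um, axial_fwhm_um, focal_depth_um,
            depth_of_focus_um, attenuation_length_um, max_visible_depth_um)
  if (any(vals <= 0) || out_of_focus_growth < 0)
    pam_stop("validation", "psf parameters must be positive")
  structure(list(lateral_fwhm_focus_um = lateral_fwhm_focus_um,
                 axial_fwhm_um = axial_fwhm_um,
                 focal_depth_um = focal_depth_um,
                 depth_of_focus_um = depth_of_focus_um,
                 out_of_focus_growth = out_of_focus_growth,
                 attenuation_length_um = attenuation_length_um,
                 max_visible_depth_um = max_visible_depth_um),
            class = "psf_model")
}

#' Default system PSFs
#'
#' The dual-system figures: OR-PAM 12 um lateral at focus / 27 um axial,
#' visible to ~1 mm; AR-PAM 85 um lateral / 27 um axial, visible to ~1.9 mm;
#' the 5 MHz deep-AR system 590 um lateral / 150 um axial.
#' @name default_psfs
#' @return a `psf_model`
NULL

#' @rdname default_psfs
#' @export
psf_or <- function() psf_model(12, 27, focal_depth_um = 500,
                               depth_of_focus_um = 400,
                               out_of_focus_growth = 0.01,
                               max_visible_depth_um = 1000)

#' @rdname default_psfs
#' @export
psf_ar <- function() psf_model(85, 27, focal_depth_um = 500,
                               depth_of_focus_um = 1500,
                               out_of_focus_growth = 0.002,
                               max_visible_depth_um = 1900)

#' @rdname default_psfs
#' @export
psf_deep_ar <- function() psf_model(590, 150, focal_depth_um = 2000,
                                    depth_of_focus_um = 3000,
                                    out_of_focus_growth = 0.001,
                                    attenuation_length_um = 3000,
                                    max_visible_depth_um = 5000)

#' Acquisition noise model
#'
#' @param gaussian_sigma additive Gaussian noise standard deviation as a
#'   fraction of full scale
#' @param salt_pepper_density fraction of pixels replaced by 0 or full scale
#'   (the impulse noise seen on OR acquisitions)
#' @return a `noise_model`
#' @export
noise_model <- function(gaussian_sigma = 0.01, salt_pepper_density = 0) {
  if (gaussian_sigma < 0 || salt_pepper_density < 0 ||
      salt_pepper_density >= 1)
    pam_stop("validation", "need sigma >= 0 and 0 <= density < 1")
  structure(list(gaussian_sigma = gaussian_sigma,
                 salt_pepper_density = salt_pepper_density),
            class = "noise_model")
}

#' Default voxel pitches (micrometres)
#'
#' Desk-scale grid: 10 um lateral, 20 um depth.
#' @param dx,dy,dz pitches in micrometres
#' @return named list of pitches
#' @export
pitch_spec <- function(dx = 10, dy = 10, dz = 20) {
  if (any(c(dx, dy, dz) <= 0)) pam_stop("validation", "pitches must be > 0")
  list(dx = dx, dy = dy, dz = dz)
}

# rasterize one tube segment: stamp voxels within radius of the segment
stamp_segment <- function(vol, p0, p1, radius_um, value, pitches) {
  d <- dim(vol)
  n_pts <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) /
                             (min(pitches$dx, pitches$dz) / 2)))
  ts <- seq(0, 1, length.out = n_pts)
  rx <- ceiling(radius_um / pitches$dx); ry <- ceiling(radius_um / pitches$dy)
  rz <- ceiling(radius_um / pitches$dz)
  for (t in ts) {
    c_um <- p0 + t * (p1 - p0)
    ci <- c(round(c_um[2] / pitches$dy), round(c_um[1] / pitches$dx),
            round(c_um[3] / pitches$dz)) + 1
    yr <- max(1, ci[1] - ry):min(d[1], ci[1] + ry)
    xr <- max(1, ci[2] - rx):min(d[2], ci[2] + rx)
    zr <- max(1, ci[3] - rz):min(d[3], ci[3] + rz)
    if (!length(yr) || !length(xr) || !length(zr)) next
    dy2 <- ((yr - 1) * pitches$dy - c_um[2])^2
    dx2 <- ((xr - 1) * pitches$dx - c_um[1])^2
    dz2 <- ((zr - 1) * pitches$dz - c_um[3])^2
    dist2 <- outer(outer(dy2, dx2, `+`), dz2, `+`)
    sel <- dist2 <= radius_um^2
    sub <- vol[yr, xr, zr, drop = FALSE]
    sub[sel] <- value
    vol[yr, xr, zr] <- sub
  }
  vol
}

#' Generate a ground-truth absorber volume
#'
#' Binary-times-absorption occupancy of the phantom geometry on the voxel
#' grid. Deterministic given the seed.
#'
#' @param spec a [phantom_spec()]
#' @param pitches a [pitch_spec()]
#' @param seed integer seed
#' @return a `TRUTH` [pam_volume()]
#' @export
make_truth_volume <- function(spec, pitches = pitch_spec(), seed = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext <- spec$extent_um
  d <- c(max(2L, round(ext[2] / pitches$dy)),
         max(2L, round(ext[1] / pitches$dx)),
         max(2L, round(ext[3] / pitches$dz)))
  vol <- array(0, d)
  set.seed(as.integer(seed %% 2^31))
  if (spec$kind == "hairs") {
    r <- spec$hair_diameter_um / 2
    zr <- spec$hair_depth_range_um
    y_pos <- ext[2] * (seq_len(spec$n_hairs)) / (spec$n_hairs + 1)
    n_seg <- 24L
    for (k in seq_len(spec$n_hairs)) {
      xs <- seq(0, ext[1], length.out = n_seg + 1)
      zs <- zr[1] + (zr[2] - zr[1]) * xs / ext[1]
      for (i in seq_len(n_seg)) {
        vol <- stamp_segment(vol, c(xs[i], y_pos[k], zs[i]),
                             c(xs[i + 1], y_pos[k], zs[i + 1]),
                             r, spec$absorption, pitches)
      }
    }
  } else {
    step_um <- 4 * min(pitches$dx, pitches$dz)
    max_steps <- ceiling(2 * ext[1] / step_um)
    grow <- function(pos, dir, diam, depth_budget) {
      for (s in seq_len(max_steps)) {
        if (depth_budget <= 0) break
        nxt <- pos + dir * step_um
        if (any(nxt < 0) || any(nxt > ext)) break
        vol <<- stamp_segment(vol, pos, nxt, diam / 2, spec$absorption,
                              pitches)
        pos <- nxt
        perturb <- rnorm(3, 0, spec$tortuosity)
        perturb[3] <- perturb[3] * 0.4     # vessels run mostly laterally
        dir <- dir + perturb
        dir <- dir / sqrt(sum(dir^2))
        diam <- max(spec$diameter_range_um[1], diam * 0.995)
        if (runif(1) < spec$branch_prob && depth_budget > 1) {
          bdir <- dir + rnorm(3, 0, 0.8); bdir <- bdir / sqrt(sum(bdir^2))
          grow(pos, bdir, diam * 0.7, depth_budget - 1)
        }
      }
    }
    for (k in seq_len(spec$n_seeds)) {
      pos <- c(runif(1, 0.05, 0.3) * ext[1], runif(1, 0.2, 0.8) * ext[2],
               runif(1, 0.15, 0.6) * ext[3])
      ang <- runif(1, -0.4, 0.4)
      dir <- c(cos(ang), sin(ang), runif(1, -0.1, 0.1))
      dir <- dir / sqrt(sum(dir^2))
      grow(pos, dir, runif(1, spec$diameter_range_um[1],
                           spec$diameter_range_um[2]), 3L)
    }
  }
  pam_volume(clamp01(vol), dx = pitches$dx, dy = pitches$dy,
             dz = pitches$dz, modality = "TRUTH",
             value_scale = "float_unit")
}

# dense 1D Gaussian convolution matrix (rows normalized); near-zero sigma
# degenerates to the identity
gauss_conv_matrix <- function(n, sigma_px) {
  if (sigma_px < 1e-3) return(diag(n))
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) dnorm(i - j, sd = sigma_px))
  K / rowSums(K)
}

lateral_fwhm_at <- function(psf, z_um) {
  off <- pmax(0, abs(z_um - psf$focal_depth_um) - psf$depth_of_focus_um / 2)
  psf$lateral_fwhm_focus_um * pmax(1, 1 + psf$out_of_focus_growth * off)
}

#' Scan a ground-truth volume through a PSF and noise model
#'
#' Depth-dependent lateral 2D Gaussian blur (slice by slice, so the blur is
#' shift-variant along depth only), axial 1D Gaussian blur, exponential
#' depth attenuation, a hard visibility cutoff, then additive Gaussian noise
#' followed by salt-and-pepper impulses, clipped to `[0, 1]`. Deterministic
#' given the seed.
#'
#' @param truth a `TRUTH` [pam_volume()]
#' @param psf a [psf_model()]
#' @param noise a [noise_model()]
#' @param seed integer seed for the noise draws
#' @param modality modality tag of the output volume
#' @return a [pam_volume()] of the scanned modality
#' @export
simulate_scan <- function(truth, psf, noise = noise_model(0, 0), seed = 0L,
                          modality = "AR") {
  stopifnot(inherits(truth, "pam_volume"))
  if (truth$modality != "TRUTH")
    pam_stop("validation", "simulate_scan expects a TRUTH volume")
  d <- dim(truth$data)
  z_um <- (seq_len(d[3]) - 1) * truth$dz
  sig_lat_px_x <- sigma_from_fwhm(lateral_fwhm_at(psf, z_um)) / truth$dx
  sig_lat_px_y <- sigma_from_fwhm(lateral_fwhm_at(psf, z_um)) / truth$dy
  out <- array(0, d)
  # lateral blur per depth slice
  for (z in seq_len(d[3])) {
    Ky <- gauss_conv_matrix(d[1], sig_lat_px_y[z])
    Kx <- gauss_conv_matrix(d[2], sig_lat_px_x[z])
    out[, , z] <- Ky %*% truth$data[, , z] %*% t(Kx)
  }
  # axial blur
  Kz <- gauss_conv_matrix(d[3], sigma_from_fwhm(psf$axial_fwhm_um) / truth$dz)
  m <- matrix(out, nrow = d[1] * d[2], ncol = d[3])
  out <- array(m %*% t(Kz), d)
  # depth attenuation and hard visibility cutoff
  decay <- exp(-z_um / psf$attenuation_length_um)
  decay[z_um > psf$max_visible_depth_um] <- 0
  out <- sweep(out, 3, decay, `*`)
  # noise
  set.seed(as.integer(seed %% 2^31))
  if (noise$gaussian_sigma > 0)
    out <- out + array(rnorm(length(out), 0, noise$gaussian_sigma), d)
  if (noise$salt_pepper_density > 0) {
    n_bad <- round(noise$salt_pepper_density * length(out))
    idx <- sample.int(length(out), n_bad)
    out[idx] <- rep_len(c(0, 1), n_bad)[sample.int(n_bad)]
  }
  pam_volume(clamp01(out), dx = truth$dx, dy = truth$dy, dz = truth$dz,
             modality = match.arg(modality, PAM_MODALITIES),
             value_scale = "float_unit")
}

#' Simulate a co-registered AR/OR dataset with provenance
#'
#' Each of `n_volumes` ground-truth phantoms is scanned twice — once with
#' the AR PSF, once with the OR PSF — so every pair is intrinsically
#' co-registered. The provenance record carries all parameters and derived
#' seeds plus content signatures of every volume.
#'
#' @param spec a [phantom_spec()]
#' @param psf_ar,psf_or the two [psf_model()]s
#' @param noise_ar,noise_or per-modality [noise_model()]s
#' @param n_volumes number of phantom volumes
#' @param pitches a [pitch_spec()]
#' @param seed master seed; per-volume seeds are derived from it
#' @return list with elements `truth`, `ar`, `or` (lists of volumes) and
#'   `provenance` (a tibble)
#' @export
make_dataset <- function(spec, psf_ar = psf_ar(), psf_or = psf_or(),
                         noise_ar = noise_model(0.02, 0),
                         noise_or = noise_model(0.005, 0.005),
                         n_volumes = 1L, pitches = pitch_spec(),
                         seed = 0L) {
  if (n_volumes < 1) pam_stop("validation", "n_volumes must be >= 1")
  truth <- vector("list", n_volumes)
  ar <- vector("list", n_volumes); or <- vector("list", n_volumes)
  prov <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    s_truth <- derive_seed(seed, paste0("truth_", i))
    s_ar <- derive_seed(seed, paste0("scan_ar_", i))
    s_or <- derive_seed(seed, paste0("scan_or_", i))
    truth[[i]] <- make_truth_volume(spec, pitches, s_truth)
    ar[[i]] <- simulate_scan(truth[[i]], psf_ar, noise_ar, s_ar, "AR")
    or[[i]] <- simulate_scan(truth[[i]], psf_or, noise_or, s_or, "OR")
    prov[[i]] <- tibble(
      volume = i, seed_truth = s_truth, seed_ar = s_ar, seed_or = s_or,
      sig_truth = content_signature(truth[[i]]$data),
      sig_ar = content_signature(ar[[i]]$data),
      sig_or = content_signature(or[[i]]$data))
  }
  list(truth = truth, ar = ar, or = or,
       provenance = dplyr::bind_rows(prov))
}

#' Resolution calibration target: a straight tube along the slow-scan axis
#'
#' A tube running along y pierces every b-scan at one `(x, z)` point, so a
#' lateral profile through it measures the in-plane lateral resolution —
#' the standard target for PSF/FWHM calibration of the simulator and of
#' trained enhancement models.
#'
#' @param n_x,n_y,n_z grid size
#' @param pitches a [pitch_spec()]
#' @param x_um,z_um tube centre position, micrometres
#' @param diameter_um tube diameter, micrometres
#' @param absorption tube amplitude in `(0, 1]`
#' @return a `TRUTH` [pam_volume()]
#' @export
make_tube_truth <- function(n_x = 64L, n_y = 16L, n_z = 64L,
                            pitches = pitch_spec(), x_um = NULL,
                            z_um = NULL, diameter_um = 20,
                            absorption = 1) {
  x_um <- x_um %||% ((n_x - 1) / 2 * pitches$dx)
  z_um <- z_um %||% ((n_z - 1) / 2 * pitches$dz)
  vol <- array(0, c(n_y, n_x, n_z))
  xs <- (seq_len(n_x) - 1) * pitches$dx
  zs <- (seq_len(n_z) - 1) * pitches$dz
  r2 <- (diameter_um / 2)^2
  mask <- outer((xs - x_um)^2, (zs - z_um)^2, `+`) <= r2
  if (!any(mask)) {
    ix <- which.min(abs(xs - x_um)); iz <- which.min(abs(zs - z_um))
    mask[ix, iz] <- TRUE                     # sub-voxel tube -> point chain
  }
  for (y in seq_len(n_y)) vol[y, , ][mask] <- absorption
  pam_volume(vol, dx = pitches$dx, dy = pitches$dy, dz = pitches$dz,
             modality = "TRUTH", value_scale = "float_unit")
}
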