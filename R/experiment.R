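# Desk-scale enhancement-recovery experiment: the package's end-to-end
# scientific check. Simulated co-registered AR/OR vessel pairs train a
# compact GAN; held-out pairs and a held-out calibration tube then measure
# whether the enhanced output (a) is closer to OR than the AR input in L1,
# (b) has a fitted tube FWHM nearer the OR value than the AR value, and
# (c) is more similar to the ground truth (SSIM) than the AR input —
# the desk-scale analogue of recovering OR-like resolution from AR scans.

#' Run the desk-scale enhancement-recovery experiment
#'
#' Simulates training and held-out volumes with the [demo_config()] study
#' conditions (64 x 64 b-scans at 10/20 um pitch, 80 um AR vs 12 um OR
#' lateral blur, ~20 um vessels), trains a compact model, and evaluates
#' recovery on data the model never saw.
#'
#' @param seed global seed; all stage seeds derive from it
#' @param mode `"cgan"` (paired) or `"cyclegan"` (unpaired)
#' @param epochs training epochs
#' @param n_volumes training phantom volumes (25 b-scans each)
#' @param n_holdout held-out phantom volumes for evaluation
#' @param base_filters generator/discriminator base filters
#' @param verbose print epoch lines
#' @return list with `model`, `metrics` (one-row tibble) and `tube`
#'   (per-modality tube FWHM tibble)
#' @export
run_recovery_experiment <- function(seed = 1L, mode = c("cgan", "cyclegan"),
                                    epochs = 12L, n_volumes = 8L,
                                    n_holdout = 2L, base_filters = 8L,
                                    verbose = FALSE) {
  mode <- match.arg(mode)
  cfg <- demo_config(seed = seed, mode = mode, epochs = epochs,
                     n_volumes = n_volumes)
  pitches <- do.call(pitch_spec, cfg$pitches)
  spec <- do.call(phantom_spec, cfg$phantom)
  psfa <- psf_from_config(cfg$psf$ar)
  psfo <- psf_from_config(cfg$psf$or)
  noia <- noise_from_config(cfg$noise$ar)
  noio <- noise_from_config(cfg$noise$or)
  sim <- make_dataset(spec, psfa, psfo, noia, noio,
                      n_volumes + n_holdout, pitches,
                      derive_seed(seed, "recovery_sim"))
  cat_vol <- function(vols, idx) {
    data <- do.call(abind3, lapply(vols[idx], `[[`, "data"))
    v1 <- vols[[idx[1]]]
    pam_volume(data, v1$dx, v1$dy, v1$dz, v1$modality, v1$value_scale)
  }
  tr_idx <- seq_len(n_volumes)
  ho_idx <- n_volumes + seq_len(n_holdout)
  patch <- cfg$preprocess$patch_size
  ar_tr <- cat_vol(sim$ar, tr_idx); or_tr <- cat_vol(sim$or, tr_idx)
  tcfg_args <- cfg$train
  tcfg_args$mode <- NULL
  tcfg_args$seed <- derive_seed(seed, "recovery_train")
  tcfg <- do.call(train_config, tcfg_args)
  gspec <- do.call(generator_spec, utils::modifyList(
    cfg$model, list(base_filters = base_filters)))
  model <- if (mode == "cgan") {
    train_cgan(build_paired(ar_tr, or_tr, patch, patch), gspec, cfg = tcfg,
               verbose = verbose)
  } else {
    train_cyclegan(build_unpaired(ar_tr, or_tr, patch, patch,
                                  derive_seed(seed, "recovery_pools")),
                   gspec, cfg = tcfg, verbose = verbose)
  }
  # held-out pair recovery: L1 to OR and SSIM to truth, slice-averaged
  l1_ar <- l1_gen <- ssim_ar <- ssim_gen <- 0
  n_sl <- 0L
  for (v in ho_idx) {
    gen <- enhance_volume(sim$ar[[v]], model, patch, patch)
    for (y in seq_len(dim(sim$ar[[v]]$data)[1])) {
      a <- bscan_slice(sim$ar[[v]], y); o <- bscan_slice(sim$or[[v]], y)
      g <- bscan_slice(gen, y); tr <- bscan_slice(sim$truth[[v]], y)
      l1_ar <- l1_ar + mean(abs(a - o)); l1_gen <- l1_gen + mean(abs(g - o))
      ssim_ar <- ssim_ar + ssim(a, tr); ssim_gen <- ssim_gen + ssim(g, tr)
      n_sl <- n_sl + 1L
    }
  }
  tube <- tube_fwhm_comparison(model, psfa, psfo, noia, noio, pitches,
                               patch, seed)
  metrics <- tibble(
    mode = mode, epochs = epochs, n_train_pairs = dim(ar_tr$data)[1],
    l1_ar = l1_ar / n_sl, l1_generated = l1_gen / n_sl,
    ssim_ar_truth = ssim_ar / n_sl, ssim_generated_truth = ssim_gen / n_sl,
    fwhm_ar_um = tube$fwhm_um[tube$image == "AR"],
    fwhm_or_um = tube$fwhm_um[tube$image == "OR"],
    fwhm_generated_um = tube$fwhm_um[tube$image == "generated"])
  list(model = model, metrics = metrics, tube = tube)
}

# scan a held-out calibration tube with both PSFs, enhance the AR scan, and
# fit the lateral FWHM of each on a MAP profile across the tube
tube_fwhm_comparison <- function(model, psf_ar, psf_or, noise_ar, noise_or,
                                 pitches, patch, seed) {
  truth <- make_tube_truth(n_x = patch, n_y = 24L, n_z = patch,
                           pitches = pitches,
                           z_um = psf_ar$focal_depth_um, diameter_um = 20)
  ar <- simulate_scan(truth, psf_ar, noise_ar,
                      derive_seed(seed, "tube_ar"), "AR")
  or <- simulate_scan(truth, psf_or, noise_or,
                      derive_seed(seed, "tube_or"), "OR")
  gen <- enhance_volume(ar, model, patch, patch)
  iz <- round(psf_ar$focal_depth_um / pitches$dz) + 1L
  fit_one <- function(vol) {
    # lateral profile at the tube depth, averaged over slow-scan rows (the
    # tube is y-invariant, so averaging suppresses noise without widening)
    prof <- tibble(position_um = (seq_len(dim(vol$data)[2]) - 1) * vol$dx,
                   value = colMeans(vol$data[, , iz]))
    fit_gaussian(prof)$fwhm_um
  }
  tibble(image = c("AR", "generated", "OR"),
         fwhm_um = c(fit_one(ar), fit_one(gen), fit_one(or)))
}
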