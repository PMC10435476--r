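test_that("hair phantoms tilt linearly in depth and occupy the grid", {
  spec <- phantom_spec(kind = "hairs", extent_um = c(1000, 300, 2200),
                      n_hairs = 3, hair_diameter_um = 150,
                      hair_depth_range_um = c(100, 2000))
  v <- make_truth_volume(spec, pitch_spec(20, 20, 20), seed = 1)
  expect_gt(mean(v$data > 0), 0)
  # centroid depth of occupied voxels increases along x
  d <- dim(v$data)
  zc <- sapply(seq_len(d[2]), function(x) {
    w <- v$data[, x, ]
    if (sum(w) == 0) NA else sum(t(w) * (seq_len(d[3]) - 1) * 20) / sum(w)
  })
  ok <- !is.na(zc)
  expect_gt(stats::cor(which(ok), zc[ok]), 0.99)
  expect_gt(zc[max(which(ok))], zc[min(which(ok))] + 1500)
})

test_that("hair cross-section chord width matches the cylinder diameter", {
  # 150 um hair at 5 um pitch: the chord through the centreline spans
  # 150/5 = 30 pixels (+1 for inclusive voxel-centre coverage)
  spec <- phantom_spec(kind = "hairs", extent_um = c(200, 400, 500),
                      n_hairs = 1, hair_diameter_um = 150,
                      hair_depth_range_um = c(250, 250))
  v <- make_truth_volume(spec, pitch_spec(5, 5, 5), seed = 2)
  iz <- 250 / 5 + 1
  ix <- dim(v$data)[2] %/% 2
  chord <- sum(v$data[, ix, iz] > 0)
  expect_gte(chord, 29)
  expect_lte(chord, 31)
})

test_that("truth volumes are pure functions of the seed", {
  spec <- phantom_spec(kind = "vessels", extent_um = c(400, 200, 600))
  p <- pitch_spec(10, 10, 20)
  expect_identical(make_truth_volume(spec, p, 5)$data,
                   make_truth_volume(spec, p, 5)$data)
  expect_false(identical(make_truth_volume(spec, p, 5)$data,
                         make_truth_volume(spec, p, 6)$data))
})

test_that("geometry that does not fit the extent errors", {
  expect_error(phantom_spec(kind = "hairs", extent_um = c(400, 200, 500),
                            hair_depth_range_um = c(100, 600)),
               class = "pamgan_error_geometry")
})

test_that("a delta absorber scans to the configured PSF width", {
  p <- pitch_spec(10, 10, 20)
  tr <- array(0, c(9, 64, 64)); tr[5, 33, 26] <- 1   # z = 500 um (focal)
  truth <- pam_volume(tr, 10, 10, 20, "TRUTH")
  for (fwhm in c(85, 12)) {
    psf <- psf_model(fwhm, 27, focal_depth_um = 500,
                     depth_of_focus_um = 1500,
                     attenuation_length_um = 1500,
                     max_visible_depth_um = 1900)
    sc <- simulate_scan(truth, psf, noise_model(0, 0), 1, "AR")
    prof <- tibble::tibble(position_um = (0:63) * 10,
                           value = sc$data[5, , 26])
    expect_lt(abs(fit_gaussian(prof)$fwhm_um - fwhm), 10)  # one pitch
  }
})

test_that("depth attenuation follows the exponential law", {
  p <- pitch_spec(10, 10, 20)
  tr <- array(0, c(3, 16, 120))
  tr[2, 8, 26] <- 1    # z = 500 um
  tr[2, 8, 76] <- 1    # z = 1500 um = focal + 1000
  truth <- pam_volume(tr, 10, 10, 20, "TRUTH")
  psf <- psf_model(40, 27, focal_depth_um = 500,
                   depth_of_focus_um = 1e6,       # uniform blur with depth
                   out_of_focus_growth = 0,
                   attenuation_length_um = 1500,
                   max_visible_depth_um = 1e6)
  sc <- simulate_scan(truth, psf, noise_model(0, 0), 1, "AR")
  peak1 <- max(sc$data[2, , 20:32])
  peak2 <- max(sc$data[2, , 70:82])
  expect_equal(peak2 / peak1, exp(-1000 / 1500), tolerance = 0.02)
})

test_that("the identity-PSF limit reproduces the truth volume", {
  truth <- make_tube_truth(32, 8, 32, pitch_spec(10, 10, 20),
                           diameter_um = 30)
  psf <- psf_model(1e-6, 1e-6, focal_depth_um = 100,
                   depth_of_focus_um = 1e9, out_of_focus_growth = 0,
                   attenuation_length_um = 1e12,
                   max_visible_depth_um = 1e9)
  sc <- simulate_scan(truth, psf, noise_model(0, 0), 1, "AR")
  expect_lt(max(abs(sc$data - truth$data)), 1e-6)
})

test_that("noise injection is seeded and respects the density", {
  truth <- make_tube_truth(32, 4, 32, pitch_spec(10, 10, 20))
  nm <- noise_model(0.01, 0.01)
  a <- simulate_scan(truth, psf_ar(), nm, 9, "AR")
  b <- simulate_scan(truth, psf_ar(), nm, 9, "AR")
  expect_identical(a$data, b$data)
  expect_false(identical(a$data,
                         simulate_scan(truth, psf_ar(), nm, 10, "AR")$data))
  expect_true(all(a$data >= 0 & a$data <= 1))
  expect_error(noise_model(-1, 0), class = "pamgan_error_validation")
  expect_error(noise_model(0, 1), class = "pamgan_error_validation")
})

test_that("resolution ordering truth <= OR <= AR holds for seeded phantoms", {
  p <- pitch_spec(10, 10, 20)
  for (seed in 1:3) {
    # single-voxel line target: a finite box and a fitted Gaussian measure
    # width differently, so the ordering is only well-posed for a structure
    # below both systems' resolution
    truth <- make_tube_truth(64, 8, 64, p, x_um = 310, z_um = 500,
                             diameter_um = 10)
    width <- function(vol) {
      prof <- tibble::tibble(position_um = (0:63) * 10,
                             value = colMeans(vol$data[, , 26]))
      fit_gaussian(prof)$fwhm_um
    }
    tp <- colMeans(truth$data[, , 26])
    w_t <- sum(tp > max(tp) / 2) * 10
    or <- simulate_scan(truth, psf_or(), noise_model(0, 0), seed, "OR")
    ar <- simulate_scan(truth, psf_ar(), noise_model(0, 0), seed, "AR")
    w_or <- width(or); w_ar <- width(ar)
    expect_lte(w_t, w_or + 1e-9)
    expect_lt(w_or, w_ar)
  }
})

test_that("deep structures appear only in AR scans (visibility cutoff)", {
  p <- pitch_spec(10, 10, 20)
  # tube at 1500 um: beyond OR visibility (1000) but within AR (1900)
  deep <- make_tube_truth(32, 6, 100, p, z_um = 1500, diameter_um = 30)
  or <- simulate_scan(deep, psf_or(), noise_model(0, 0), 1, "OR")
  ar <- simulate_scan(deep, psf_ar(), noise_model(0, 0), 1, "AR")
  expect_equal(max(or$data), 0)
  expect_gt(max(ar$data), 0.01)
})

test_that("energy ordering: shorter attenuation length, less energy", {
  truth <- make_tube_truth(32, 4, 48, pitch_spec(10, 10, 20),
                           z_um = 500, diameter_um = 30)
  energy <- function(att) {
    psf <- psf_model(40, 27, attenuation_length_um = att,
                     max_visible_depth_um = 1e6,
                     depth_of_focus_um = 1e6, out_of_focus_growth = 0)
    sc <- simulate_scan(truth, psf, noise_model(0, 0), 1, "AR")
    apply(sc$data, 3, sum)
  }
  e_long <- energy(2000); e_short <- energy(500)
  expect_true(all(e_short <= e_long + 1e-12))
})

test_that("make_dataset produces co-registered deterministic pairs", {
  spec <- phantom_spec(kind = "vessels", extent_um = c(320, 100, 640),
                      n_seeds = 2)
  p <- pitch_spec(10, 10, 20)
  ds <- make_dataset(spec, psf_ar(), psf_or(), noise_model(0.01, 0),
                     noise_model(0.01, 0.005), n_volumes = 5,
                     pitches = p, seed = 3)
  expect_length(ds$ar, 5)
  expect_length(ds$or, 5)
  for (i in 1:5)
    expect_identical(dim(ds$ar[[i]]$data), dim(ds$or[[i]]$data))
  expect_equal(nrow(ds$provenance), 5)
  ds2 <- make_dataset(spec, psf_ar(), psf_or(), noise_model(0.01, 0),
                      noise_model(0.01, 0.005), n_volumes = 5,
                      pitches = p, seed = 3)
  expect_identical(ds$ar[[2]]$data, ds2$ar[[2]]$data)
  expect_identical(ds$provenance, ds2$provenance)
})
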