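test_that("SNR follows 10 log10 of the ROI power ratio", {
  img <- matrix(0, 10, 10)
  img[1:3, 1:3] <- 1                       # signal power 1
  img[8:10, 8:10] <- sqrt(0.1)             # noise power 0.1
  s <- roi(0, 3, 0, 3)
  n <- roi(7, 10, 7, 10, role = "background")
  expect_equal(snr_db(img, s, n), 10)
  expect_equal(snr_db(img, s, s), 0)       # identical ROIs
  expect_error(snr_db(img, s, roi(4, 6, 4, 6)),
               class = "pamgan_error_undefined_metric")
})

test_that("SNR and CNR match naive-loop recomputation on random images", {
  set.seed(10)
  for (k in 1:20) {
    img <- matrix(runif(30 * 30, 0.1, 1), 30, 30)
    s <- roi(2, 12, 3, 13); b <- roi(18, 28, 15, 29, "background")
    img[3:12, 4:13] <- img[3:12, 4:13] + 1    # guarantee mu_s > mu_b
    img <- img / max(img)
    # independent double-loop oracle
    p_s <- 0; n_s <- 0
    for (i in 3:12) for (j in 4:13) { p_s <- p_s + img[i, j]^2; n_s <- n_s + 1 }
    p_b <- 0; vals <- c()
    for (i in 19:28) for (j in 16:29) { p_b <- p_b + img[i, j]^2
      vals <- c(vals, img[i, j]) }
    snr_ref <- 10 * log10((p_s / n_s) / (p_b / length(vals)))
    cnr_ref <- 10 * log10((mean(img[3:12, 4:13]) - mean(vals)) / sd(vals))
    expect_equal(snr_db(img, s, b), snr_ref, tolerance = 1e-12)
    expect_equal(cnr_db(img, s, b), cnr_ref, tolerance = 1e-12)
  }
})

test_that("CNR is the printed 10 log10 amplitude formula", {
  img <- matrix(0, 4, 6)
  img[1, 1:5] <- c(0, 0, 20, 20, 10) / 255   # mean 10, sd exactly 10
  img[3:4, ] <- 110 / 255
  sig <- roi(2, 4, 0, 6)
  bg <- roi(0, 1, 0, 5, "background")
  expect_equal(cnr_db(img * 255, sig, bg), 10)
  # equal means are an unusable ROI choice
  flat <- matrix(c(0.1, 0.2, 0.1, 0.2), 2, 2)
  expect_error(cnr_db(rbind(flat, flat), roi(0, 2, 0, 2),
                      roi(2, 4, 0, 2, "background")),
               class = "pamgan_error_undefined_metric")
})

test_that("SNR/CNR are invariant under positive rescaling", {
  set.seed(11)
  img <- matrix(runif(20 * 20, 0.2, 0.9), 20, 20)
  img[2:6, 2:6] <- img[2:6, 2:6] + 2
  s <- roi(1, 6, 1, 6); b <- roi(12, 19, 12, 19, "background")
  for (c in c(0.05, 0.5, 3)) {
    expect_equal(snr_db(img * c, s, b), snr_db(img, s, b),
                 tolerance = 1e-10)
    expect_equal(cnr_db(img * c, s, b), cnr_db(img, s, b),
                 tolerance = 1e-10)
  }
})

test_that("SSIM has unit diagonal, symmetry and sane ordering", {
  set.seed(12)
  x <- matrix(runif(40 * 40), 40, 40)
  expect_equal(ssim(x, x), 1)
  y <- matrix(runif(40 * 40), 40, 40)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_lt(ssim(x, 1 - x), ssim(x, x))
  expect_gte(ssim(x, y), -1)
  expect_lte(ssim(x, y), 1)
  expect_error(ssim(x, y[1:20, ]), class = "pamgan_error_validation")
  expect_error(ssim(x, y, window = 8), class = "pamgan_error_validation")
})

test_that("SSIM agrees with the scikit-image reference on random pairs", {
  set.seed(13)
  for (k in 1:10) {
    a <- matrix(runif(24 * 24), 24, 24)
    b <- matrix(pmin(pmax(a + rnorm(24 * 24, 0, 0.2), 0), 1), 24, 24)
    expect_equal(ssim(a, b), skimage_ssim(a, b), tolerance = 1e-6)
  }
})

test_that("cw_ssim is a bounded similarity with unit diagonal tendency", {
  set.seed(14)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- matrix(runif(32 * 32), 32, 32)
  expect_gt(cw_ssim(x, x), 0.99)
  expect_lt(cw_ssim(x, y), cw_ssim(x, x))
  expect_true(cw_ssim(x, y) >= 0 && cw_ssim(x, y) <= 1)
})

test_that("profiles carry physical positions and respect bounds", {
  img <- matrix(seq_len(100) / 100, 10, 10)
  p <- extract_profile(img, 3, along = "row", pitch_um = 5)
  expect_equal(p$position_um, seq(0, 45, by = 5))
  expect_equal(p$value, img[3, ])
  pc <- extract_profile(img, 4, along = "col", pitch_um = 2,
                        axis = "axial")
  expect_equal(pc$value, img[, 4])
  expect_equal(attr(pc, "axis"), "axial")
  expect_error(extract_profile(img, 11, "row"),
               class = "pamgan_error_validation")
})

test_that("Gaussian fits recover sigma on clean and noisy profiles", {
  x <- 0:80
  clean <- tibble::tibble(position_um = x,
                          value = exp(-(x - 40)^2 / (2 * 100)))
  f <- fit_gaussian(clean)
  expect_equal(f$fwhm_um, 2 * sqrt(2 * log(2)) * 10, tolerance = 1e-3)
  expect_equal(f$fwhm_um / f$sigma_um, 2 * sqrt(2 * log(2)),
               tolerance = 1e-9)
  # Monte-Carlo recovery at 1% noise
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    noisy <- tibble::tibble(position_um = x,
                            value = exp(-(x - 40)^2 / 200) +
                              rnorm(81, 0, 0.01))
    worst <- max(worst, abs(fit_gaussian(noisy)$sigma_um - 10) / 10)
  }
  expect_lt(worst, 0.05)
  expect_error(fit_gaussian(tibble::tibble(position_um = x,
                                           value = rep(1, 81))),
               class = "pamgan_error_fit")
  expect_error(fit_gaussian(tibble::tibble(position_um = 1:3,
                                           value = c(1, 2, 1))),
               class = "pamgan_error_validation")
})

test_that("tidy() flattens a gaussian_fit", {
  x <- 0:40
  f <- fit_gaussian(tibble::tibble(position_um = x,
                                   value = exp(-(x - 20)^2 / 50)))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$fwhm_um, f$fwhm_um)
  expect_equal(td$n, 41)
})

test_that("compare_images reports the simulator resolution ordering", {
  p <- pitch_spec(10, 10, 20)
  truth <- make_tube_truth(64, 10, 64, p, z_um = 500, diameter_um = 20)
  ar <- simulate_scan(truth, psf_ar(), noise_model(0.005, 0), 1, "AR")
  or <- simulate_scan(truth, psf_or(), noise_model(0.005, 0), 1, "OR")
  bsc <- function(v) matrix(v$data[5, , ], 64, 64)
  rep <- compare_images(
    list(AR = bsc(ar), OR = bsc(or)),
    signal = roi(24, 40, 20, 32),
    background = roi(0, 10, 50, 63, "background"),
    profile_line = 26, along = "col", pitch_um = 10)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep), 2)
  expect_gt(rep$fwhm_um[rep$image == "AR"],
            rep$fwhm_um[rep$image == "OR"])
  expect_equal(rep$ssim[rep$image == "OR"], 1)   # reference vs itself
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rep, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$snr_db, rep$snr_db, tolerance = 1e-12)
  expect_equal(back$fwhm_um, rep$fwhm_um, tolerance = 1e-12)
})
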