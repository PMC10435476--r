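test_that("normalization is global over the volume and idempotent", {
  set.seed(1)
  arr <- array(0, c(2, 4, 4))
  arr[1, , ] <- matrix(sample(0:200, 16), 4, 4)
  arr[1, 1, 1] <- 200          # global maximum lives in slice 1
  arr[2, , ] <- 5              # slice 2 maximum is 5
  v <- normalize_volume(pam_volume(arr, 1, 1, 1, "AR",
                                   value_scale = "uint8"))
  expect_equal(max(v$data), 1)
  expect_equal(v$data, arr / 200)
  # second slice scaled by the global (not per-slice) maximum
  expect_equal(unique(as.numeric(v$data[2, , ])), 5 / 200)
  # idempotent on an already-unit volume
  expect_equal(normalize_volume(v)$data, v$data)
})

test_that("normalization is scale-invariant and rejects zero volumes", {
  v <- rand_volume(2, 4, 6, seed = 5)
  scaled <- pam_volume(v$data * 0.37, v$dx, v$dy, v$dz, v$modality)
  expect_equal(normalize_volume(v)$data, normalize_volume(scaled)$data)
  expect_error(normalize_volume(pam_volume(array(0, c(2, 2, 2)),
                                           1, 1, 1, "AR")),
               class = "pamgan_error_normalization")
})

test_that("bandpass envelope recovers in-band tone amplitude", {
  band <- band_spec(10, 90, 250)
  fs <- 250   # MHz
  t <- seq(0, 4, by = 1 / fs)   # microseconds
  tone <- 0.8 * sin(2 * pi * 50 * t)   # 50 MHz, mid-band
  env <- bandpass_envelope(tone, band)
  core <- env[200:(length(env) - 200)]   # away from edges
  expect_true(all(env >= 0))
  expect_lt(max(abs(core - 0.8)) / 0.8, 0.05)
})

test_that("bandpass attenuates far out-of-band tones by >= 20 dB", {
  band <- band_spec(10, 90, 250)
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  inband <- bandpass_envelope(sin(2 * pi * 50 * t), band)
  lowband <- bandpass_envelope(sin(2 * pi * 1 * t), band)  # 0.1x low edge
  core <- 200:(length(t) - 200)
  atten_db <- 20 * log10(mean(inband[core]) / mean(lowband[core]))
  expect_gt(atten_db, 20)
})

test_that("bandpass envelope handles zero input, matrices and bad bands", {
  band <- band_spec(10, 90, 250)
  expect_equal(bandpass_envelope(numeric(500), band), numeric(500))
  m <- matrix(rnorm(500 * 3), 500, 3)
  env <- bandpass_envelope(m, band)
  expect_equal(dim(env), dim(m))
  expect_true(all(env >= 0))
  expect_error(band_spec(90, 10, 250), class = "pamgan_error_validation")
  expect_error(band_spec(10, 200, 250), class = "pamgan_error_validation")
})

test_that("patch tiling is deterministic with inward-shifted edge tiles", {
  b <- matrix(runif(512 * 512), 512, 512)
  s <- extract_patches(b, 256, 256)
  expect_equal(dim(s$patches)[3], 4)
  expect_equal(s$origins$x0, c(0, 256, 0, 256))
  expect_equal(s$origins$z0, c(0, 0, 256, 256))
  # 300x512: last x-origin shifted inward to 300 - 256 = 44
  b2 <- matrix(runif(300 * 512), 300, 512)
  s2 <- extract_patches(b2, 256, 256)
  expect_equal(dim(s2$patches)[3], 4)
  expect_equal(sort(unique(s2$origins$x0)), c(0, 44))
  expect_equal(sort(unique(s2$origins$z0)), c(0, 256))
  # jitter disabled: identical tilings on repeated calls
  expect_identical(extract_patches(b2, 256, 256), s2)
  # full coverage by construction
  cover <- matrix(0, 300, 512)
  for (i in seq_len(4)) {
    xi <- s2$origins$x0[i] + 1:256; zi <- s2$origins$z0[i] + 1:256
    cover[xi, zi] <- 1
  }
  expect_true(all(cover == 1))
  expect_error(extract_patches(b2, 0), class = "pamgan_error_validation")
})

test_that("uint8 conversion uses round-half-up and inverts", {
  expect_equal(to_uint8(c(0, 1)), c(0, 255))
  expect_equal(to_uint8(0.5), 128)
  expect_equal(to_uint8(127.5 / 255), 128)
  u <- to_uint8(matrix(runif(64), 8, 8))
  expect_equal(to_uint8(u / 255), u)
  expect_error(to_uint8(1.2), class = "pamgan_error_validation")
})

test_that("paired assembly aligns origins and counts pairs", {
  v <- rand_volume(10, 32, 32, seed = 6)
  o <- pam_volume(v$data, v$dx, v$dy, v$dz, "OR")
  d <- build_paired(v, o, patch_size = 16, stride = 16)
  expect_equal(dim(d$A)[3], 10 * 4)   # 10 slices x 4 patches each
  expect_equal(d$A, d$O)              # identical inputs -> equal members
  expect_equal(nrow(d$index), 40)
  expect_true(all(d$index$source_index == rep(1:10, each = 4)))
  mis <- pam_volume(array(0.1, c(9, 32, 32)), v$dx, v$dy, v$dz, "OR")
  expect_error(build_paired(v, mis, 16, 16),
               class = "pamgan_error_registration")
})

test_that("unpaired pools are seeded, decoupled and full-sized", {
  a <- rand_volume(5, 32, 32, seed = 7, modality = "AR")
  o <- rand_volume(7, 32, 32, seed = 8, modality = "OR")
  u1 <- build_unpaired(a, o, 16, 16, seed = 42)
  u2 <- build_unpaired(a, o, 16, 16, seed = 42)
  expect_identical(u1$A, u2$A)
  expect_identical(u1$O, u2$O)
  expect_equal(dim(u1$A)[3], 5 * 4)
  expect_equal(dim(u1$O)[3], 7 * 4)
  u3 <- build_unpaired(a, o, 16, 16, seed = 43)
  expect_false(identical(u1$A, u3$A))
})
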