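tiny_gen <- generator_spec(n_res_blocks = 1, base_filters = 4,
                           n_downsamples = 1)
# 16x16 toys need a shallow discriminator (the default 3 stride-2 stages
# would shrink them below the 4x4 kernels)
tiny_d2 <- discriminator_spec(base_filters = 4, n_layers = 2,
                              in_channels = 2)
tiny_d1 <- discriminator_spec(base_filters = 4, n_layers = 2,
                              in_channels = 1)

test_that("the learning-rate schedule decays by the configured factor", {
  cfg <- train_config(epochs = 5, lr = 2e-4, lr_decay_factor = 0.5,
                      lr_decay_epochs = 2, seed = 1)
  expect_equal(sapply(1:5, function(e) lr_at_epoch(cfg, e)),
               c(2e-4, 2e-4, 1e-4, 1e-4, 1e-4))
  cfg2 <- train_config(lr_decay_epochs = c(100, 150))
  expect_equal(lr_at_epoch(cfg2, 200), 2e-4 * 0.25)
  d <- constant_paired(0.3, 0.3, size = 16)
  m <- train_cgan(d, tiny_gen, disc_spec = tiny_d2,
                  cfg = train_config(epochs = 3, lr_decay_epochs = 2,
                                     l1_weight = 100, seed = 1))
  expect_equal(m$history$lr, c(2e-4, 2e-4, 1e-4))
  expect_true(all(diff(m$history$lr) <= 0))
})

test_that("cGAN L1 decreases toward a constant target", {
  d <- constant_paired(0.3, 0.3, size = 16)
  m <- train_cgan(d, tiny_gen, disc_spec = tiny_d2,
                  cfg = train_config(epochs = 5, l1_weight = 100,
                                     lr_decay_epochs = integer(),
                                     seed = 2))
  l1 <- m$history$loss_recon
  expect_equal(nrow(m$history), 5)
  expect_lt(l1[5], l1[1])
  expect_lt(mean(diff(l1)), 0)     # decreasing trend
})

test_that("training is a pure function of (data, specs, config)", {
  d <- constant_paired(0.25, 0.45, size = 16)
  cfg <- train_config(epochs = 2, l1_weight = 100, seed = 11)
  m1 <- train_cgan(d, tiny_gen, disc_spec = tiny_d2, cfg = cfg)
  m2 <- train_cgan(d, tiny_gen, disc_spec = tiny_d2, cfg = cfg)
  expect_identical(m1$generator$layers, m2$generator$layers)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(gan_generate(m1$generator, x),
                   gan_generate(m2$generator, x))
  expect_identical(m1$history$loss_g_adv, m2$history$loss_g_adv)
})

test_that("CycleGAN cycle loss shrinks on a trivial fixed point", {
  v <- pam_volume(array(0.4, c(1, 16, 16)), 10, 10, 20, "AR")
  o <- pam_volume(array(0.4, c(1, 16, 16)), 10, 10, 20, "OR")
  u <- build_unpaired(v, o, 16, 16, seed = 1)
  m <- train_cyclegan(u, tiny_gen, disc_spec = tiny_d1,
                      cfg = train_config(epochs = 5, cycle_weight = 10,
                                         lr_decay_epochs = integer(),
                                         seed = 3))
  expect_equal(nrow(m$history), 5)
  cyc <- m$history$loss_recon
  expect_lt(cyc[5], cyc[1])
})

test_that("swapping unpaired pools swaps the learned direction", {
  # domain A is dark (0.2), domain O bright (0.8); the forward generator
  # should move its input toward the target domain, and swapping the pools
  # reverses that direction
  a <- pam_volume(array(0.2, c(1, 16, 16)), 10, 10, 20, "AR")
  o <- pam_volume(array(0.8, c(1, 16, 16)), 10, 10, 20, "OR")
  cfg <- train_config(epochs = 6, cycle_weight = 1,
                      lr_decay_epochs = integer(), seed = 4)
  x <- matrix(0.2, 16, 16)
  m_fwd <- train_cyclegan(build_unpaired(a, o, 16, 16, 1), tiny_gen,
                          disc_spec = tiny_d1,
                          cfg = cfg)
  m_swp <- train_cyclegan(build_unpaired(o, a, 16, 16, 1), tiny_gen,
                          disc_spec = tiny_d1,
                          cfg = cfg)
  y_fwd <- mean(gan_generate(m_fwd$generator, x))
  y_swp <- mean(gan_generate(m_swp$generator, matrix(0.8, 16, 16)))
  expect_gt(y_fwd, 0.4)    # pushed toward the bright domain
  expect_lt(y_swp, 0.6)    # pushed toward the dark domain
})

test_that("checkpoints restore generator outputs bit-for-bit", {
  d <- constant_paired(0.3, 0.5, size = 16)
  m <- train_cgan(d, tiny_gen, disc_spec = tiny_d2,
                  cfg = train_config(epochs = 2, l1_weight = 100,
                                     seed = 5))
  path <- tempfile(fileext = ".rds")
  checkpoint(m, path)
  r <- restore_model(path)
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(gan_generate(r$generator, x),
                   gan_generate(m$generator, x))
  expect_equal(r$epoch, 2)
  expect_identical(r$history, m$history)
  # spec mismatch is an explicit error
  other <- generator_spec(n_res_blocks = 2, base_filters = 4,
                          n_downsamples = 1)
  expect_error(restore_model(path, gen_spec = other),
               class = "pamgan_error_spec_mismatch")
  expect_silent(restore_model(path, gen_spec = tiny_gen))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(restore_model(bad), class = "pamgan_error_checkpoint")
})

test_that("divergence and empty datasets raise classed errors", {
  ns <- asNamespace("pamgan")
  expect_error(ns$check_finite_loss(1, NaN, epoch = 7),
               class = "pamgan_error_training_divergence")
  expect_error(train_cgan(constant_paired(), tiny_gen,
                          disc_spec = discriminator_spec(in_channels = 1),
                          cfg = train_config(epochs = 1)),
               class = "pamgan_error_validation")
  expect_error(train_config(lr = -1), class = "pamgan_error_validation")
  expect_error(train_config(lr_decay_factor = 0),
               class = "pamgan_error_validation")
})

test_that("tidy/glance/autoplot expose the training history", {
  d <- constant_paired(0.3, 0.4, size = 16)
  m <- train_cgan(d, tiny_gen, disc_spec = tiny_d2,
                  cfg = train_config(epochs = 2, l1_weight = 100,
                                     seed = 6))
  h <- tidy(m)
  expect_s3_class(h, "tbl_df")
  expect_named(h, c("epoch", "loss_g_adv", "loss_recon", "loss_d", "lr",
                    "seconds"))
  g <- glance(m)
  expect_equal(nrow(g), 1)
  expect_equal(g$epochs, 2)
  expect_equal(g$n_param_generator, count_parameters(m$generator))
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
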