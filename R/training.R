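# Adversarial training. The paired objective is
#   L_cGAN(A,O) = E[log D(A,O)] + E[log(1 - D(A, G(A)))] + lambda * E|O - G(A)|_1
# optimized as a minimax game (G minimizes, D maximizes); the unpaired
# scheme runs the same objective in both directions with two generators and
# adds cycle-consistency L1 terms |F(G(a)) - a| and |G(F(o)) - o|.
# Adversarial terms are binary cross-entropy on sigmoid decisions, computed
# on logits for numerical stability. Batch size 1, alternating D/G updates
# with a 1:1 step ratio.

#' Training configuration
#'
#' Defaults follow the reference schedule: Adam at learning rate 0.0002
#' decayed by a factor 0.5, an L1 weight of 0.01, unsigned-8-bit-normalized
#' patches and batch size 1. The decay epochs are a repository convention.
#' An L1
#' weight of 100 — the convention of the pix2pix/CycleGAN model families —
#' is the documented alternative profile used by the desk-scale demos.
#'
#' @param epochs number of training epochs
#' @param lr initial Adam learning rate
#' @param lr_decay_factor multiplicative decay factor in `(0, 1]`
#' @param lr_decay_epochs epochs after which the decay fires
#' @param l1_weight weight of the paired L1 term
#' @param cycle_weight weight of the cycle-consistency terms
#' @param batch_size patches per optimizer step (1)
#' @param seed master seed: weight init and per-epoch shuffles derive
#'   from it
#' @param beta1,beta2 Adam moment decay rates
#' @param adv_loss adversarial criterion: `"bce"` (binary cross-entropy on
#'   sigmoid decisions) or `"lsgan"` (least-squares on the raw decision
#'   scores, a common stabilization)
#' @return a `train_config`
#' @export
train_config <- function(epochs = 200L, lr = 2e-4, lr_decay_factor = 0.5,
                         lr_decay_epochs = c(100L, 150L), l1_weight = 0.01,
                         cycle_weight = 10, batch_size = 1L, seed = 0L,
                         beta1 = 0.5, beta2 = 0.999,
                         adv_loss = c("bce", "lsgan")) {
  adv_loss <- match.arg(adv_loss)
  if (lr <= 0) pam_stop("validation", "lr must be positive")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    pam_stop("validation", "lr_decay_factor must be in (0, 1]")
  if (l1_weight < 0 || cycle_weight < 0)
    pam_stop("validation", "loss weights must be >= 0")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 l1_weight = l1_weight, cycle_weight = cycle_weight,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 adv_loss = adv_loss),
            class = "train_config")
}

#' Learning rate at a given epoch under the step-decay schedule
#'
#' @param cfg a [train_config()]
#' @param epoch 1-based epoch index
#' @return the learning rate in force during `epoch`
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay_factor^sum(cfg$lr_decay_epochs < epoch)
}

softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
sigm <- function(z) 1 / (1 + exp(-z))

# BCE-with-logits against a constant target (0 or 1); returns loss and dz
bce_logits <- function(z, target) {
  n <- length(z)
  loss <- mean(target * softplus(-z) + (1 - target) * softplus(z))
  list(loss = loss, dz = (sigm(z) - target) / n)
}

# adversarial criterion dispatcher: BCE on sigmoid decisions or
# least-squares directly on the decision scores
adv_terms <- function(z, target, kind) {
  if (kind == "bce") return(bce_logits(z, target))
  n <- length(z)
  list(loss = mean((z - target)^2), dz = 2 * (z - target) / n)
}

check_finite_loss <- function(..., epoch) {
  if (!all(is.finite(c(...))))
    pam_stop("training_divergence",
             sprintf("non-finite loss at epoch %d", epoch))
}

concat_ch <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], 2L))
}

new_history_row <- function(epoch, g_adv, recon, d, lr, secs) {
  tibble(epoch = epoch, loss_g_adv = g_adv, loss_recon = recon,
         loss_d = d, lr = lr, seconds = secs)
}

#' Train a paired conditional GAN (AR patches labeled with OR patches)
#'
#' The discriminator judges channel-concatenated (source, candidate) pairs;
#' the generator minimizes its adversarial term plus `l1_weight` times the
#' L1 distance to the paired target. Fully seeded: the same datasets,
#' specs and config reproduce the run bit-for-bit.
#'
#' @param data a `paired_dataset` from [build_paired()]
#' @param gen_spec a [generator_spec()]
#' @param disc_spec a [discriminator_spec()] with `in_channels = 2`
#' @param cfg a [train_config()]
#' @param verbose print one line per epoch
#' @return a `pam_gan` model (generator, discriminator, config, history)
#' @export
train_cgan <- function(data, gen_spec, disc_spec = discriminator_spec(
                         base_filters = gen_spec$base_filters,
                         in_channels = 2L),
                       cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(data, "paired_dataset"))
  n <- dim(data$A)[3]
  if (n == 0) pam_stop("validation", "empty paired dataset")
  if (disc_spec$in_channels != 2L)
    pam_stop("validation", "conditioned discriminator needs in_channels = 2")
  G <- build_generator(gen_spec, derive_seed(cfg$seed, "cgan_gen"))
  D <- build_discriminator(disc_spec, derive_seed(cfg$seed, "cgan_disc"))
  stG <- adam_init(G$layers); stD <- adam_init(D$layers)
  t_adam <- 0L
  history <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_at_epoch(cfg, epoch)
    set.seed(derive_seed(cfg$seed, paste0("cgan_epoch_", epoch)))
    order_idx <- sample.int(n)
    acc <- c(g_adv = 0, l1 = 0, d = 0)
    for (i in order_idx) {
      A <- array(data$A[, , i], c(dim(data$A)[1:2], 1L))
      O <- array(data$O[, , i], c(dim(data$O)[1:2], 1L))
      t_adam <- t_adam + 1L
      gf <- net_forward(G$layers, A)
      fake <- gf$y
      # --- discriminator step
      fr <- net_forward(D$layers, concat_ch(A[, , 1], O[, , 1]))
      ff <- net_forward(D$layers, concat_ch(A[, , 1], fake[, , 1]))
      br <- adv_terms(fr$y, 1, cfg$adv_loss)
      bf <- adv_terms(ff$y, 0, cfg$adv_loss)
      gr <- net_backward(D$layers, fr$caches, 0.5 * array(br$dz, dim(fr$y)))
      gf2 <- net_backward(D$layers, ff$caches, 0.5 * array(bf$dz, dim(ff$y)))
      up <- adam_step(D$layers, grads_add(gr$grads, gf2$grads), stD, lr,
                      cfg$beta1, cfg$beta2, t_adam)
      D$layers <- up$layers; stD <- up$state
      # --- generator step (against the updated discriminator)
      fd <- net_forward(D$layers, concat_ch(A[, , 1], fake[, , 1]))
      ba <- adv_terms(fd$y, 1, cfg$adv_loss)
      bd <- net_backward(D$layers, fd$caches, array(ba$dz, dim(fd$y)))
      dfake <- bd$dx[, , 2, drop = FALSE]
      l1 <- mean(abs(fake - O))
      dfake <- dfake + cfg$l1_weight * sign(fake - O) / length(fake)
      bg <- net_backward(G$layers, gf$caches, dfake)
      up <- adam_step(G$layers, bg$grads, stG, lr, cfg$beta1, cfg$beta2,
                      t_adam)
      G$layers <- up$layers; stG <- up$state
      check_finite_loss(br$loss, bf$loss, ba$loss, l1, epoch = epoch)
      acc <- acc + c(ba$loss, l1, br$loss + bf$loss)
    }
    acc <- acc / n
    history[[epoch]] <- new_history_row(
      epoch, acc[["g_adv"]], acc[["l1"]], acc[["d"]], lr,
      proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %3d  adv %.4f  L1 %.4f  D %.4f  lr %g",
                      epoch, acc[["g_adv"]], acc[["l1"]], acc[["d"]], lr))
  }
  structure(list(kind = "cgan", generator = G, discriminator = D,
                 config = cfg, history = dplyr::bind_rows(history),
                 epoch = cfg$epochs),
            class = "pam_gan")
}

#' Train an unpaired cycle-consistent GAN
#'
#' Four networks: forward generator `G` (AR to OR), backward generator
#' (OR to AR), and one unconditioned discriminator per domain. Each step
#' optimizes adversarial terms in both directions plus `cycle_weight` times
#' the two cycle-consistency L1 terms.
#'
#' @param data an `unpaired_dataset` from [build_unpaired()]
#' @param gen_spec a [generator_spec()] (used for both generators)
#' @param disc_spec a [discriminator_spec()] with `in_channels = 1`
#' @param cfg a [train_config()]
#' @param verbose print one line per epoch
#' @return a `pam_gan` with `generator` (A to O), `generator_back`
#'   (O to A) and both discriminators
#' @export
train_cyclegan <- function(data, gen_spec, disc_spec = discriminator_spec(
                             base_filters = gen_spec$base_filters,
                             in_channels = 1L),
                           cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(data, "unpaired_dataset"))
  nA <- dim(data$A)[3]; nO <- dim(data$O)[3]
  if (nA == 0 || nO == 0) pam_stop("validation", "empty unpaired pool")
  if (disc_spec$in_channels != 1L)
    pam_stop("validation",
             "cycle discriminators are unconditioned (in_channels = 1)")
  G <- build_generator(gen_spec, derive_seed(cfg$seed, "cyc_gen_f"))
  Fb <- build_generator(gen_spec, derive_seed(cfg$seed, "cyc_gen_b"))
  DO <- build_discriminator(disc_spec, derive_seed(cfg$seed, "cyc_disc_o"))
  DA <- build_discriminator(disc_spec, derive_seed(cfg$seed, "cyc_disc_a"))
  stG <- adam_init(G$layers); stF <- adam_init(Fb$layers)
  stDO <- adam_init(DO$layers); stDA <- adam_init(DA$layers)
  t_adam <- 0L
  n_iter <- max(nA, nO)
  history <- vector("list", cfg$epochs)
  hw1 <- function(pool, i) array(pool[, , i], c(dim(pool)[1:2], 1L))
  disc_step <- function(Dn, st, real, fake, lr) {
    fr <- net_forward(Dn$layers, real)
    ff <- net_forward(Dn$layers, fake)
    br <- adv_terms(fr$y, 1, cfg$adv_loss)
    bf <- adv_terms(ff$y, 0, cfg$adv_loss)
    gr <- net_backward(Dn$layers, fr$caches, 0.5 * array(br$dz, dim(fr$y)))
    gf <- net_backward(Dn$layers, ff$caches, 0.5 * array(bf$dz, dim(ff$y)))
    up <- adam_step(Dn$layers, grads_add(gr$grads, gf$grads), st, lr,
                    cfg$beta1, cfg$beta2, t_adam)
    list(layers = up$layers, state = up$state, loss = br$loss + bf$loss)
  }
  adv_grad <- function(Dn, fake) {
    fd <- net_forward(Dn$layers, fake)
    ba <- adv_terms(fd$y, 1, cfg$adv_loss)
    bd <- net_backward(Dn$layers, fd$caches, array(ba$dz, dim(fd$y)))
    list(dx = bd$dx, loss = ba$loss)
  }
  for (epoch in seq_len(cfg$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_at_epoch(cfg, epoch)
    set.seed(derive_seed(cfg$seed, paste0("cyc_epoch_", epoch)))
    ia <- rep_len(sample.int(nA), n_iter)
    io <- rep_len(sample.int(nO), n_iter)
    acc <- c(g_adv = 0, cyc = 0, d = 0)
    for (s in seq_len(n_iter)) {
      a <- hw1(data$A, ia[s]); o <- hw1(data$O, io[s])
      t_adam <- t_adam + 1L
      # forward passes (cached for the joint generator step)
      f_go <- net_forward(G$layers, a);  fake_o <- f_go$y
      f_fa <- net_forward(Fb$layers, o); fake_a <- f_fa$y
      # --- discriminators
      dso <- disc_step(DO, stDO, o, fake_o, lr)
      DO$layers <- dso$layers; stDO <- dso$state
      dsa <- disc_step(DA, stDA, a, fake_a, lr)
      DA$layers <- dsa$layers; stDA <- dsa$state
      # --- joint generator step
      f_rec_a <- net_forward(Fb$layers, fake_o)  # F(G(a))
      f_rec_o <- net_forward(G$layers, fake_a)   # G(F(o))
      advO <- adv_grad(DO, fake_o)
      advA <- adv_grad(DA, fake_a)
      cyc_a <- mean(abs(f_rec_a$y - a))
      cyc_o <- mean(abs(f_rec_o$y - o))
      d_rec_a <- cfg$cycle_weight * sign(f_rec_a$y - a) / length(a)
      d_rec_o <- cfg$cycle_weight * sign(f_rec_o$y - o) / length(o)
      bF1 <- net_backward(Fb$layers, f_rec_a$caches, d_rec_a)
      bG1 <- net_backward(G$layers, f_rec_o$caches, d_rec_o)
      dfake_o <- advO$dx + bF1$dx
      dfake_a <- advA$dx + bG1$dx
      bG2 <- net_backward(G$layers, f_go$caches, dfake_o)
      bF2 <- net_backward(Fb$layers, f_fa$caches, dfake_a)
      upG <- adam_step(G$layers, grads_add(bG1$grads, bG2$grads), stG, lr,
                       cfg$beta1, cfg$beta2, t_adam)
      G$layers <- upG$layers; stG <- upG$state
      upF <- adam_step(Fb$layers, grads_add(bF1$grads, bF2$grads), stF, lr,
                       cfg$beta1, cfg$beta2, t_adam)
      Fb$layers <- upF$layers; stF <- upF$state
      check_finite_loss(advO$loss, advA$loss, cyc_a, cyc_o, dso$loss,
                        dsa$loss, epoch = epoch)
      acc <- acc + c(advO$loss + advA$loss, cyc_a + cyc_o,
                     (dso$loss + dsa$loss) / 2)
    }
    acc <- acc / n_iter
    history[[epoch]] <- new_history_row(
      epoch, acc[["g_adv"]], acc[["cyc"]], acc[["d"]], lr,
      proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %3d  adv %.4f  cyc %.4f  D %.4f  lr %g",
                      epoch, acc[["g_adv"]], acc[["cyc"]], acc[["d"]], lr))
  }
  structure(list(kind = "cyclegan", generator = G, generator_back = Fb,
                 discriminator = DO, discriminator_back = DA,
                 config = cfg, history = dplyr::bind_rows(history),
                 epoch = cfg$epochs),
            class = "pam_gan")
}

#' @export
print.pam_gan <- function(x, ...) {
  cat(sprintf("<pam_gan> %s, %d epochs trained\n", x$kind, x$epoch))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: adv %.4f, recon %.4f, D %.4f\n",
                last$loss_g_adv, last$loss_recon, last$loss_d))
  }
  invisible(x)
}

#' Tidy the per-epoch training history of a model
#'
#' @param x a `pam_gan`
#' @param ... unused
#' @return tibble with one row per epoch (losses, learning rate, seconds)
#' @export
tidy.pam_gan <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x a `pam_gan`
#' @param ... unused
#' @return tibble: kind, epochs, parameter counts, final losses
#' @export
glance.pam_gan <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(kind = x$kind, epochs = x$epoch,
         n_param_generator = count_parameters(x$generator),
         n_param_discriminator = count_parameters(x$discriminator),
         loss_g_adv = last$loss_g_adv, loss_recon = last$loss_recon,
         loss_d = last$loss_d, final_lr = last$lr)
}

#' Generics for model summaries
#'
#' `tidy()` returns a per-epoch tibble, `glance()` a one-row summary.
#' @param x object to summarize
#' @param ... passed to methods
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot training loss curves by epoch
#'
#' @param object a `pam_gan`
#' @param ... unused
#' @return a ggplot of the loss-vs-epoch curves
#' @method autoplot pam_gan
#' @export
autoplot.pam_gan <- function(object, ...) {
  df <- tidyr_longer(object$history)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = sprintf("%s training", object$kind))
}

# tiny pivot helper (keeps tidyr out of Imports)
tidyr_longer <- function(h) {
  dplyr::bind_rows(
    tibble(epoch = h$epoch, loss = "generator adversarial",
           value = h$loss_g_adv),
    tibble(epoch = h$epoch, loss = "L1 / cycle", value = h$loss_recon),
    tibble(epoch = h$epoch, loss = "discriminator", value = h$loss_d))
}

#' Save a trained model to disk
#'
#' The checkpoint is a single serialized file embedding the network specs,
#' seeds, config, history and epoch; [restore_model()] reproduces generator
#' outputs bit-for-bit.
#'
#' @param model a `pam_gan`
#' @param path output file path
#' @return `path`, invisibly
#' @export
checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pam_gan"))
  saveRDS(list(format = "pamgan-checkpoint-v1", model = model), path)
  invisible(path)
}

#' Restore a trained model from a checkpoint
#'
#' @param path checkpoint path
#' @param gen_spec optional [generator_spec()]; if supplied, restoring a
#'   checkpoint whose generator spec differs is an error
#' @return the `pam_gan` model
#' @export
restore_model <- function(path, gen_spec = NULL) {
  obj <- try(readRDS(path), silent = TRUE)
  if (inherits(obj, "try-error") || !is.list(obj) ||
      !identical(obj$format, "pamgan-checkpoint-v1"))
    pam_stop("checkpoint", sprintf("not a valid checkpoint: %s", path))
  model <- obj$model
  if (!is.null(gen_spec) &&
      !identical(unclass(model$generator$spec), unclass(gen_spec)))
    pam_stop("spec_mismatch",
             "checkpoint generator spec does not match the expected spec")
  model
}
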