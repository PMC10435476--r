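# Network topologies: a ResNet-block encoder/decoder generator and a
# Markovian (patch) discriminator. Capacity is fully configurable so the
# full-scale topology (9 residual blocks, 64 base filters, 256x256 patches)
# and desk-scale variants share one code path.

#' Generator topology specification
#'
#' Encoder (7x7 stem + strided 3x3 convolutions), `n_res_blocks` residual
#' blocks with identity skips at the bottleneck, and a mirrored
#' transposed-convolution decoder. The full-scale configuration is 9
#' residual blocks with 64 base filters on single-channel 256x256 patches.
#'
#' @param n_res_blocks number of residual blocks (>= 1; full scale 9)
#' @param base_filters filters after the stem (>= 4; full scale 64)
#' @param n_downsamples number of stride-2 encoder stages (default 2)
#' @param in_channels,out_channels image channels (1 for PAM b-scans)
#' @param norm `"instance"` (batch-size-1 training) or `"none"`
#' @param padding `"reflect"` or `"zero"` stem/res-block padding
#' @return a `generator_spec`
#' @export
generator_spec <- function(n_res_blocks = 9L, base_filters = 64L,
                           n_downsamples = 2L, in_channels = 1L,
                           out_channels = 1L,
                           norm = c("instance", "none"),
                           padding = c("reflect", "zero")) {
  norm <- match.arg(norm); padding <- match.arg(padding)
  if (n_res_blocks < 1) pam_stop("validation", "n_res_blocks must be >= 1")
  if (base_filters < 4) pam_stop("validation", "base_filters must be >= 4")
  structure(list(n_res_blocks = as.integer(n_res_blocks),
                 base_filters = as.integer(base_filters),
                 n_downsamples = as.integer(n_downsamples),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 norm = norm, padding = padding),
            class = "generator_spec")
}

#' Discriminator topology specification
#'
#' Stacked stride-2 4x4 convolutions with leaky-ReLU activations ending in
#' a 1-channel decision layer. `decision_mode = "patch_map"` keeps the
#' spatial grid of local (Markovian) decisions; `"global_scalar"` pools the
#' grid to a single decision value.
#'
#' @param base_filters filters in the first layer
#' @param n_layers number of stride-2 stages (>= 1; 3 gives the classic
#'   70x70 receptive field)
#' @param in_channels input channels (2 for a conditioned source+candidate
#'   pair, 1 for an unconditioned candidate)
#' @param decision_mode `"patch_map"` or `"global_scalar"`
#' @return a `discriminator_spec`
#' @export
discriminator_spec <- function(base_filters = 64L, n_layers = 3L,
                               in_channels = 2L,
                               decision_mode = c("patch_map",
                                                 "global_scalar")) {
  decision_mode <- match.arg(decision_mode)
  if (n_layers < 1) pam_stop("validation", "n_layers must be >= 1")
  structure(list(base_filters = as.integer(base_filters),
                 n_layers = as.integer(n_layers),
                 in_channels = as.integer(in_channels),
                 decision_mode = decision_mode),
            class = "discriminator_spec")
}

res_block <- function(ch, padding, norm) {
  pad_layers <- function() {
    if (padding == "reflect") list(new_reflect(1L), new_conv(ch, ch, 3L, 1L, 0L))
    else list(new_conv(ch, ch, 3L, 1L, 1L))
  }
  layers <- c(pad_layers(),
              if (norm == "instance") list(new_inorm(ch)),
              list(new_relu()),
              pad_layers(),
              if (norm == "instance") list(new_inorm(ch)))
  new_resblock(layers)
}

#' Build a generator network
#'
#' Parameter initialization (Gaussian, sd 0.02) is deterministic given the
#' seed. The instantiated network maps any `(H, W)` single-channel input
#' with `H`, `W` divisible by `2^n_downsamples` to a same-shape output in
#' `[0, 1]` (tanh output rescaled).
#'
#' @param spec a [generator_spec()]
#' @param seed integer seed for weight initialization
#' @return a `pam_generator`
#' @export
build_generator <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(as.integer(seed %% 2^31))
  bf <- spec$base_filters
  norm <- spec$norm
  maybe_norm <- function(ch) if (norm == "instance") list(new_inorm(ch))
  layers <- list()
  # stem
  if (spec$padding == "reflect") {
    layers <- c(layers, list(new_reflect(3L),
                             new_conv(spec$in_channels, bf, 7L, 1L, 0L)))
  } else {
    layers <- c(layers, list(new_conv(spec$in_channels, bf, 7L, 1L, 3L)))
  }
  layers <- c(layers, maybe_norm(bf), list(new_relu()))
  ch <- bf
  for (d in seq_len(spec$n_downsamples)) {
    layers <- c(layers, list(new_conv(ch, ch * 2L, 3L, 2L, 1L)),
                maybe_norm(ch * 2L), list(new_relu()))
    ch <- ch * 2L
  }
  for (r in seq_len(spec$n_res_blocks))
    layers <- c(layers, list(res_block(ch, spec$padding, norm)))
  for (d in seq_len(spec$n_downsamples)) {
    layers <- c(layers, list(new_convt(ch, ch %/% 2L, 3L, 2L, 1L, 1L)),
                maybe_norm(ch %/% 2L), list(new_relu()))
    ch <- ch %/% 2L
  }
  if (spec$padding == "reflect") {
    layers <- c(layers, list(new_reflect(3L),
                             new_conv(ch, spec$out_channels, 7L, 1L, 0L)))
  } else {
    layers <- c(layers, list(new_conv(ch, spec$out_channels, 7L, 1L, 3L)))
  }
  layers <- c(layers, list(new_tanh01()))
  structure(list(layers = layers, spec = spec, seed = as.integer(seed)),
            class = "pam_generator")
}

#' Build a Markovian patch discriminator
#'
#' @param spec a [discriminator_spec()]
#' @param seed integer seed for weight initialization
#' @return a `pam_discriminator`
#' @export
build_discriminator <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  set.seed(as.integer(seed %% 2^31))
  bf <- spec$base_filters
  layers <- list(new_conv(spec$in_channels, bf, 4L, 2L, 1L), new_lrelu())
  ch <- bf
  if (spec$n_layers >= 2) {
    for (i in 2:spec$n_layers) {
      nxt <- min(bf * 2L^(i - 1L), bf * 8L)
      layers <- c(layers, list(new_conv(ch, nxt, 4L, 2L, 1L),
                               new_inorm(nxt), new_lrelu()))
      ch <- nxt
    }
  }
  nxt <- min(ch * 2L, bf * 8L)
  layers <- c(layers, list(new_conv(ch, nxt, 4L, 1L, 1L), new_inorm(nxt),
                           new_lrelu(),
                           new_conv(nxt, 1L, 4L, 1L, 1L)))
  structure(list(layers = layers, spec = spec, seed = as.integer(seed)),
            class = "pam_discriminator")
}

check_gen_input <- function(gen, x) {
  d <- dim(x)
  div <- 2L^gen$spec$n_downsamples
  if (d[1] %% div != 0 || d[2] %% div != 0)
    pam_stop("shape", sprintf(
      "input %dx%d not divisible by 2^n_downsamples = %d", d[1], d[2], div))
}

as_hw1 <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

#' Apply a generator to an image patch
#'
#' @param gen a `pam_generator`
#' @param x 2D matrix or `(H, W, C)` array; `H`, `W` must be divisible by
#'   `2^n_downsamples`
#' @return translated patch, same spatial shape, values in `[0, 1]`
#' @export
gan_generate <- function(gen, x) {
  stopifnot(inherits(gen, "pam_generator"))
  x <- as_hw1(x)
  check_gen_input(gen, x)
  y <- net_forward(gen$layers, x)$y
  if (dim(y)[3] == 1L) matrix(y, dim(y)[1], dim(y)[2]) else y
}

#' Apply a discriminator to a candidate (optionally with its source)
#'
#' In `patch_map` mode returns the spatial grid of sigmoid decisions; in
#' `global_scalar` mode the grid is mean-pooled to one sigmoid value (the
#' single 1x1 decision).
#'
#' @param disc a `pam_discriminator`
#' @param x candidate image (matrix) or channel-stacked `(H, W, C)` array
#'   matching `in_channels`
#' @return decision values in `(0, 1)`: a matrix (patch map) or scalar
#' @export
discriminate <- function(disc, x) {
  stopifnot(inherits(disc, "pam_discriminator"))
  x <- as_hw1(x)
  if (dim(x)[3] != disc$spec$in_channels)
    pam_stop("shape", sprintf("expected %d input channels, got %d",
                              disc$spec$in_channels, dim(x)[3]))
  z <- net_forward(disc$layers, x)$y
  if (disc$spec$decision_mode == "global_scalar")
    return(1 / (1 + exp(-mean(z))))
  matrix(1 / (1 + exp(-z)), dim(z)[1], dim(z)[2])
}

#' Count trainable parameters of a network
#'
#' @param net a `pam_generator` or `pam_discriminator`
#' @return exact count of trainable scalar parameters
#' @export
count_parameters <- function(net) {
  stopifnot(is.list(net$layers))
  sum(vapply(net$layers, layer_param_count, 1))
}

#' @export
print.pam_generator <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<pam_generator> %d res blocks, %d base filters, %d downsamples, %s norm (%s params)\n",
    s$n_res_blocks, s$base_filters, s$n_downsamples, s$norm,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.pam_discriminator <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<pam_discriminator> %d layers, %d base filters, %s mode (%s params)\n",
    s$n_layers, s$base_filters, s$decision_mode,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
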