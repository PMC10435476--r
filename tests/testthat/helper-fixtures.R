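# shared fixture builders; everything is generated in code under fixed seeds

rand_volume <- function(ny = 4, nx = 8, nz = 16, seed = 1,
                        modality = "AR") {
  set.seed(seed)
  pam_volume(array(runif(ny * nx * nz), c(ny, nx, nz)),
             dx = 10, dy = 10, dz = 20, modality = modality)
}

# generator that passes its input through untouched (no layers at all);
# used to isolate the tiling/stitching path from the network
identity_model <- function() {
  g <- build_generator(generator_spec(n_res_blocks = 1, base_filters = 4,
                                      n_downsamples = 0), seed = 0)
  g$layers <- list()
  structure(list(kind = "cgan", generator = g, discriminator = NULL,
                 config = train_config(epochs = 0),
                 history = tibble::tibble(), epoch = 0L),
            class = "pam_gan")
}

# tiny paired dataset of constant images
constant_paired <- function(value_a = 0.3, value_o = 0.3, n = 1,
                            size = 16) {
  v <- function(val) pam_volume(array(val, c(n, size, size)), 10, 10, 20,
                                "AR")
  a <- v(value_a); o <- v(value_o); o$modality <- "OR"
  build_paired(a, o, patch_size = size, stride = size)
}

# SSIM reference values from scikit-image (uniform 7x7 window, sample
# covariance), computed through the preinstalled python of this image
skimage_ssim <- function(a, b, win = 7L) {
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  utils::write.table(a, fa, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  utils::write.table(b, fb, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  code <- sprintf(paste0(
    "import numpy as np; from skimage.metrics import structural_similarity as s; ",
    "a=np.loadtxt(%s,delimiter=\",\"); b=np.loadtxt(%s,delimiter=\",\"); ",
    "print(float(s(a,b,win_size=%d,data_range=1.0,gaussian_weights=False)))"),
    shQuote(fa), shQuote(fb), win)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  as.numeric(out[length(out)])
}

python_available <- function() {
  nzchar(Sys.which("python"))
}
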