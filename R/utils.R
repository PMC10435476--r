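# internal helpers -----------------------------------------------------------

pam_stop <- function(class, msg, ...) {
  abort(msg, class = paste0("pamgan_error_", class), ...)
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    pam_stop("validation", sprintf("`%s` must be a single positive number", name))
  invisible(x)
}

#' Full width at half maximum of a Gaussian with standard deviation `sigma`
#'
#' The conversion constant `2*sqrt(2*log(2))` (~2.3548) relates a Gaussian
#' profile's sigma to its full width at half maximum.
#' @param sigma standard deviation (any length unit)
#' @return FWHM in the same unit
#' @export
fwhm_from_sigma <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' @rdname fwhm_from_sigma
#' @param fwhm full width at half maximum
#' @export
sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 32-bit FNV-1a over a character string; used to expand one global seed into
# independent per-stage seeds. Kept below 2^31 so the result is a valid R seed.
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 16777619 multiply mod 2^32 without integer overflow
    h <- (h * 16777619) %% 2^32
  }
  h %% 2^31
}

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed from the single
#' global seed plus the stage name, so one integer reproduces a whole run
#' while stages remain statistically independent.
#' @param global_seed integer global seed
#' @param stage stage name, e.g. `"simulate"`
#' @return integer seed in `[0, 2^31)`
#' @export
derive_seed <- function(global_seed, stage) {
  as.integer((fnv1a32(stage) + as.numeric(global_seed) * 2654435761) %% 2^31)
}

# compact deterministic content signature for provenance records
content_signature <- function(x) {
  v <- as.numeric(x)
  sprintf("n%d-s%.8g-q%.8g", length(v), sum(v), sum(v * v))
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
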