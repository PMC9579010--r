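# Radial spatial-frequency grid (cycles/image) for an s x s FFT layout.
fft_radial_freq <- function(s) {
  f1 <- c(0:(floor(s / 2)), -((ceiling(s / 2) - 1):1))
  fx <- outer(abs(f1), rep(1, s))
  fy <- outer(rep(1, s), abs(f1))
  sqrt(fx^2 + fy^2)
}

# Random-phase field whose Fourier amplitude scales as f^beta (beta <= 0).
power_law_field <- function(size, beta) {
  w <- matrix(rnorm(size * size), size, size)
  W <- fft(w)
  f <- fft_radial_freq(size)
  gain <- ifelse(f > 0, f^beta, 0)
  Re(fft(W * gain, inverse = TRUE)) / (size * size)
}

#' Synthesize a power-law noise image
#'
#' A random-phase image whose Fourier amplitude falls as `f^beta`
#' (`beta = -1` gives the 1/f spectrum of natural scenes; `beta = 0` gives
#' white noise), standardized to zero mean and unit SD.
#'
#' @param size Image side, pixels.
#' @param beta Spectral exponent (amplitude ~ f^beta).
#' @param seed Integer seed.
#' @return A `size` x `size` numeric matrix.
#' @export
power_law_image <- function(size = 128, beta = -1, seed = 1) {
  with_seed(seed, {
    img <- power_law_field(size, beta)
    (img - mean(img)) / sd(img)
  })
}

#' Radially averaged amplitude spectrum
#'
#' Computes the 2-D Fourier amplitude of a square luminance image, averages
#' it within log-spaced radial frequency bins, and fits the log-log slope
#' (the spectral exponent; about -1 for natural images).
#'
#' @param image Square numeric matrix, side >= 64, non-constant.
#' @param n_bins Number of log-spaced frequency bins (>= 8) between 1
#'   cycle/image and the Nyquist frequency.
#' @return A list of class `spectrum_profile`: `bins` (tibble with `freq`,
#'   the mean log-frequency of each bin back-transformed, and `amplitude`),
#'   `slope`, `slope_se`, `n_bins`.
#' @examples
#' sp <- amplitude_spectrum(power_law_image(128, beta = -1, seed = 1))
#' sp$slope  # close to -1
#' @export
amplitude_spectrum <- function(image, n_bins = 16) {
  if (!is.matrix(image) || nrow(image) != ncol(image)) {
    abort("`image` must be a square numeric matrix.")
  }
  s <- nrow(image)
  if (s < 64) abort("`image` must be at least 64 px a side.")
  if (n_bins < 8) abort("Slope fitting needs at least 8 frequency bins.")
  if (sd(image) == 0) abort("Constant image: amplitude spectrum undefined.")

  amp <- Mod(fft(image - mean(image)))
  f <- fft_radial_freq(s)
  keep <- f >= 1 & f <= s / 2
  fv <- f[keep]
  av <- amp[keep]

  edges <- exp(seq(log(1), log(s / 2), length.out = n_bins + 1))
  bin <- cut(fv, breaks = edges, include.lowest = TRUE, labels = FALSE)
  ok <- !is.na(bin)
  mean_amp <- tapply(av[ok], bin[ok], mean)
  mean_logf <- tapply(log10(fv[ok]), bin[ok], mean)
  used <- !is.na(mean_amp) & mean_amp > 0
  if (sum(used) < 8) abort("Fewer than 8 populated frequency bins.")

  fit <- stats::lm(log10(mean_amp[used]) ~ mean_logf[used])
  structure(list(
    bins = tibble(freq = 10^as.numeric(mean_logf[used]),
                  amplitude = as.numeric(mean_amp[used])),
    slope = unname(stats::coef(fit)[2]),
    slope_se = unname(summary(fit)$coefficients[2, 2]),
    n_bins = sum(used)
  ), class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat(sprintf("Radially averaged amplitude spectrum (%d bins)\n", x$n_bins))
  cat(sprintf("  log-log slope: %.3f (SE %.3f)\n", x$slope, x$slope_se))
  invisible(x)
}
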