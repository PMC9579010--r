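#' Hemodynamic response function parameters
#'
#' Parameters of the canonical double-gamma hemodynamic response function
#' (HRF): a positive gamma peak minus a scaled, later gamma undershoot.
#'
#' @param peak_delay Delay of the positive response peak, seconds.
#' @param undershoot_delay Delay of the undershoot, seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions, seconds.
#' @param undershoot_ratio Ratio of undershoot to peak amplitude.
#' @param length_s Kernel support, seconds (at least 24 s so the undershoot
#'   resolves).
#' @return A list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, length_s = 32) {
  assert_scalar_number(peak_delay, "peak_delay", lower = 1e-3)
  assert_scalar_number(undershoot_delay, "undershoot_delay", lower = 1e-3)
  assert_scalar_number(peak_dispersion, "peak_dispersion", lower = 1e-6)
  assert_scalar_number(undershoot_dispersion, "undershoot_dispersion", lower = 1e-6)
  assert_scalar_number(undershoot_ratio, "undershoot_ratio", lower = 0)
  assert_scalar_number(length_s, "length_s", lower = 24)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, length_s = length_s),
            class = "hrf_params")
}

#' Sample the double-gamma HRF kernel
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling step in seconds.
#' @return Numeric vector of kernel values at `seq(0, length_s, by = dt)`,
#'   peak-normalized so `max(kernel) == 1`.
#' @export
hrf_kernel <- function(params = hrf_params(), dt) {
  assert_scalar_number(dt, "dt", lower = 1e-6)
  t <- seq(0, params$length_s, by = dt)
  h <- dgamma(t, shape = params$peak_delay / params$peak_dispersion,
              scale = params$peak_dispersion) -
    params$undershoot_ratio *
      dgamma(t, shape = params$undershoot_delay / params$undershoot_dispersion,
             scale = params$undershoot_dispersion)
  m <- max(h)
  if (!is.finite(m) || m <= 0) abort("HRF kernel has no positive peak.")
  h / m
}
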