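# ---- shared forward model -------------------------------------------------
# Both the BOLD simulator and the pRF fitter express a voxel's noiseless
# percent-signal time course as a weighted sum of convolved event-group
# regressors: the event train of each (label, numerosity) group is sampled
# at `dt_ms`, convolved with the HRF kernel, averaged within each TR window,
# and scaled so a sustained 15-s stimulus of unit neural amplitude peaks at
# 1. Sharing this code path makes the fitter's prediction identical to the
# simulator's noiseless output.

causal_convolve <- function(u, kernel) {
  out <- stats::convolve(u, rev(kernel), type = "open")
  out[seq_along(u)]
}

tr_average <- function(x, n_per_tr) {
  m <- matrix(x, nrow = n_per_tr)
  colMeans(m)
}

# Peak of the convolved response to a sustained 15-s unit stimulus; the
# amplitude unit of the forward model (PSC at a sustained preferred-stimulus
# response).
sustained_peak <- function(hrf = hrf_params(), dt_ms = 50, block_ms = 15000) {
  dt <- dt_ms / 1000
  k <- hrf_kernel(hrf, dt)
  pad <- length(k)
  u <- c(rep(1, block_ms / dt_ms), rep(0, pad))
  max(causal_convolve(u, k) * dt)
}

# Default number of retained volumes for a timeline: task TRs plus trailing
# rest TRs (8 by default, giving the 248 retained volumes of the block runs).
default_n_timepoints <- function(timeline, n_post_trs = 8) {
  tr <- timeline_tr_ms(timeline)
  ceiling(timeline_duration_ms(timeline) / tr) + n_post_trs
}

# Convolved, TR-averaged regressors for groups of events. `groups` is a list
# of integer event-index vectors. Returns a timepoints x groups matrix in
# sustained-peak units.
event_group_regressors <- function(timeline, groups, hrf = hrf_params(),
                                   n_timepoints = NULL, dt_ms = 50) {
  tr_ms <- timeline_tr_ms(timeline)
  if (is.null(n_timepoints)) n_timepoints <- default_n_timepoints(timeline)
  if (tr_ms %% dt_ms != 0) abort("`dt_ms` must divide the TR.")
  n_per_tr <- tr_ms %/% dt_ms
  n_samples <- n_timepoints * n_per_tr
  dt <- dt_ms / 1000
  k <- hrf_kernel(hrf, dt)
  scale <- sustained_peak(hrf, dt_ms)

  out <- matrix(0, n_timepoints, length(groups))
  for (g in seq_along(groups)) {
    u <- numeric(n_samples)
    for (e in groups[[g]]) {
      i0 <- timeline$onset_ms[e] %/% dt_ms + 1L
      i1 <- min((timeline$onset_ms[e] + timeline$duration_ms[e] - 1L) %/% dt_ms + 1L,
                n_samples)
      if (i0 <= n_samples) u[i0:i1] <- 1
    }
    out[, g] <- tr_average(causal_convolve(u, k) * dt, n_per_tr) / scale
  }
  out
}

# Event groups by distinct (label, numerosity); the basis for kind-specific
# voxel responses.
stimulus_basis <- function(timeline, hrf = hrf_params(), n_timepoints = NULL,
                           dt_ms = 50) {
  key <- paste(timeline$label, timeline$numerosity, sep = "\r")
  levels <- !duplicated(key)
  lev_tbl <- tibble(label = timeline$label[levels],
                    numerosity = timeline$numerosity[levels])
  groups <- split(seq_len(nrow(timeline)), factor(key, levels = key[levels]))
  C <- event_group_regressors(timeline, groups, hrf, n_timepoints, dt_ms)
  list(levels = lev_tbl, C = C)
}

# Log-Gaussian numerosity tuning curve, peak 1 at n = mu; sigma in natural-log
# numerosity units.
log_gaussian_tuning <- function(n, mu, sigma) {
  exp(-(log(n) - log(mu))^2 / (2 * sigma^2))
}

# Neural amplitude of one voxel for each (label, numerosity) level.
level_amplitudes <- function(levels, kind, mu = NA, sigma = NA,
                             amplitude = 0, scenery_gain = 0) {
  n <- nrow(levels)
  switch(kind,
    numerosity_tuned = {
      unlabeled <- is.na(levels$numerosity) &
        !(levels$label %in% natural_categories())
      if (any(unlabeled)) {
        abort("A numerosity-tuned voxel was given events with neither a numerosity nor a visual category label.")
      }
      ifelse(!is.na(levels$numerosity),
             amplitude * log_gaussian_tuning(levels$numerosity, mu, sigma),
             scenery_gain)
    },
    scenery_responsive = ifelse(levels$label %in% natural_categories(),
                                amplitude, 0),
    visual_untuned = rep(amplitude, n),
    null = rep(0, n),
    abort(sprintf("Unknown voxel kind '%s'.", kind))
  )
}

#' Per-event neural amplitudes of a voxel
#'
#' Evaluates a voxel's neural response to every event of a timeline, before
#' hemodynamic convolution. A numerosity-tuned voxel presented `n` items
#' responds `amplitude * exp(-(ln n - ln mu)^2 / (2 sigma^2))`; for a
#' natural-image event carrying no numerosity (scenery) it responds its
#' nonspecific `scenery_gain`. A scenery-responsive voxel responds
#' `amplitude` to natural-image categories and 0 to dot displays; an untuned
#' visual voxel responds `amplitude` to every event; a null voxel responds 0.
#'
#' @param timeline An `nt_timeline`.
#' @param kind One of `"numerosity_tuned"`, `"scenery_responsive"`,
#'   `"visual_untuned"`, `"null"`.
#' @param mu,sigma Log-Gaussian tuning parameters (tuned voxels only):
#'   preferred numerosity and tuning width (natural-log units).
#' @param amplitude Response amplitude, percent signal.
#' @param scenery_gain Tuned voxels' response to no-numerosity natural
#'   images, percent signal.
#' @return A tibble with `onset_ms`, `label`, `numerosity`, `amplitude`.
#' @export
neural_timecourse <- function(timeline, kind, mu = NA, sigma = NA,
                              amplitude = 1, scenery_gain = 0) {
  stopifnot(inherits(timeline, "nt_timeline"))
  if (kind == "numerosity_tuned") {
    if (!is.finite(mu) || mu <= 0 || !is.finite(sigma) || sigma <= 0) {
      abort("Tuned voxels need `mu` > 0 and `sigma` > 0.")
    }
  }
  amp <- level_amplitudes(
    tibble(label = timeline$label, numerosity = timeline$numerosity),
    kind, mu, sigma, amplitude, scenery_gain)
  tibble(onset_ms = timeline$onset_ms, label = timeline$label,
         numerosity = timeline$numerosity, amplitude = amp)
}
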