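#' Candidate grid for pRF fitting
#'
#' Log-spaced candidate preferred numerosities and tuning widths for the
#' grid stage of the log-Gaussian pRF fit.
#'
#' @param mu_range,n_mu Preferred-numerosity range (stimulus counts) and
#'   number of grid points.
#' @param sigma_range,n_sigma Tuning-width range (natural-log numerosity
#'   units) and number of grid points.
#' @return A list of class `prf_grid` with `mu`, `sigma` vectors and the
#'   expanded `pairs` tibble.
#' @export
prf_grid <- function(mu_range = c(1, 10), n_mu = 25,
                     sigma_range = c(0.05, 3), n_sigma = 20) {
  mu <- exp(seq(log(mu_range[1]), log(mu_range[2]), length.out = n_mu))
  sigma <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                   length.out = n_sigma))
  structure(list(mu = mu, sigma = sigma,
                 pairs = tidyr::expand_grid(mu = mu, sigma = sigma)),
            class = "prf_grid")
}

#' Predicted pRF time course
#'
#' The noiseless unit-amplitude BOLD prediction of a log-Gaussian numerosity
#' pRF for a timeline: each event's neural amplitude is the tuning curve
#' evaluated at its numerosity, convolved with the HRF and averaged within
#' TRs — the identical code path the simulator uses, so a noiseless tuned
#' voxel is reproduced exactly.
#'
#' @param timeline An `nt_timeline` whose events all carry numerosities.
#' @param mu,sigma Preferred numerosity (> 0) and tuning width (> 0,
#'   natural-log units).
#' @param hrf [hrf_params()].
#' @param n_timepoints Number of retained volumes to predict (defaults to
#'   the run shape implied by the timeline).
#' @return Numeric vector of length `n_timepoints`.
#' @export
predict_prf_timecourse <- function(timeline, mu, sigma, hrf = hrf_params(),
                                   n_timepoints = NULL) {
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be positive.")
  if (!is.finite(mu) || mu <= 0) abort("`mu` must be positive.")
  if (anyNA(timeline$numerosity)) {
    abort("All events must carry a numerosity for pRF prediction.")
  }
  basis <- stimulus_basis(timeline, hrf, n_timepoints)
  g <- log_gaussian_tuning(basis$levels$numerosity, mu, sigma)
  as.numeric(basis$C %*% g)
}

# Average the signal matrices of one or more runs (they must share a shape).
average_run_signal <- function(runs) {
  if (inherits(runs, "nt_bold_run")) runs <- list(runs)
  mats <- purrr::map(runs, "signal")
  Reduce(`+`, mats) / length(mats)
}

#' Grid fit of log-Gaussian numerosity pRFs
#'
#' For every voxel, finds the `(mu, sigma)` grid pair whose prediction —
#' with amplitude and baseline fitted by ordinary least squares, amplitude
#' constrained non-negative — maximizes variance explained
#' (`VE = 1 - RSS/TSS`, clipped to [0, 1]). Candidate fits with negative
#' amplitude are assigned VE 0; constant voxel series are flagged invalid.
#'
#' @param runs One `nt_bold_run` or a list of them (averaged before
#'   fitting); all must share the localizer timeline structure.
#' @param grid A [prf_grid()].
#' @param hrf [hrf_params()].
#' @param timeline Timeline used for predictions; defaults to the first
#'   run's.
#' @return A tibble of class `nt_prf_fit`: per voxel `mu`, `sigma`,
#'   `amplitude`, `baseline`, `ve`, `valid` (plus the run's voxel metadata
#'   columns when present).
#' @export
fit_prf_grid <- function(runs, grid = prf_grid(), hrf = hrf_params(),
                         timeline = NULL) {
  if (inherits(runs, "nt_bold_run")) runs <- list(runs)
  timeline <- timeline %||% runs[[1]]$timeline
  Y <- average_run_signal(runs)
  n_t <- nrow(Y)

  basis <- stimulus_basis(timeline, hrf, n_timepoints = n_t)
  G <- vapply(seq_len(nrow(grid$pairs)), function(i) {
    log_gaussian_tuning(basis$levels$numerosity, grid$pairs$mu[i],
                        grid$pairs$sigma[i])
  }, numeric(nrow(basis$levels)))
  P <- basis$C %*% G  # timepoints x grid pairs

  p_mean <- colMeans(P)
  p_sd <- sqrt(colSums(sweep(P, 2, p_mean)^2) / (n_t - 1))
  y_mean <- colMeans(Y)
  y_sd <- sqrt(colSums(sweep(Y, 2, y_mean)^2) / (n_t - 1))
  usable_p <- p_sd > 0
  valid_y <- y_sd > 0

  Pz <- sweep(sweep(P, 2, p_mean), 2, pmax(p_sd, 1e-300), "/")
  Yz <- sweep(sweep(Y, 2, y_mean), 2, pmax(y_sd, 1e-300), "/")
  r <- crossprod(Pz, Yz) / (n_t - 1)      # grid pairs x voxels
  r[!usable_p, ] <- 0
  ve <- r^2 * (r > 0)                     # amplitude >= 0: negative r -> VE 0

  best <- max.col(t(ve), ties.method = "first")
  n_v <- ncol(Y)
  idx <- cbind(best, seq_len(n_v))
  best_r <- r[idx]
  best_ve <- ve[idx]
  amplitude <- pmax(best_r, 0) * y_sd / p_sd[best]
  baseline <- y_mean - amplitude * p_mean[best]

  out <- tibble(
    voxel = seq_len(n_v),
    mu = grid$pairs$mu[best], sigma = grid$pairs$sigma[best],
    amplitude = amplitude, baseline = baseline,
    ve = pmin(pmax(ifelse(valid_y, best_ve, 0), 0), 1),
    valid = valid_y, refined = FALSE
  )
  meta <- runs[[1]]$voxels
  if (!is.null(meta) && nrow(meta) == n_v) {
    out <- dplyr::bind_cols(dplyr::select(meta, dplyr::any_of(
      c("subject", "roi", "kind"))), out)
  }
  structure(out, class = c("nt_prf_fit", class(tibble())),
            grid = grid, timeline = timeline, hrf = hrf)
}

# VE of a single (mu, sigma) prediction against a voxel series, amplitude
# constrained non-negative.
prf_ve_single <- function(y, timeline_basis, mu, sigma) {
  g <- log_gaussian_tuning(timeline_basis$levels$numerosity, mu, sigma)
  p <- as.numeric(timeline_basis$C %*% g)
  if (sd(p) == 0 || sd(y) == 0) return(0)
  r <- cor(p, y)
  if (!is.finite(r) || r <= 0) 0 else r^2
}

#' Continuous refinement of a grid pRF fit
#'
#' Bounded local optimization of `(mu, sigma)` in log space (L-BFGS-B)
#' starting from each voxel's grid optimum. The refined fit never has lower
#' VE than the grid fit: if the optimizer fails or regresses, the grid
#' result is kept and the voxel's `refined` flag stays `FALSE`.
#'
#' @param fit An [fit_prf_grid()] result.
#' @param runs The same run(s) the grid was fitted to.
#' @param voxels Optional indices of voxels to refine (default: all valid).
#' @return The fit tibble with updated `mu`, `sigma`, `amplitude`,
#'   `baseline`, `ve`, `refined`.
#' @export
refine_prf_fit <- function(fit, runs, voxels = NULL) {
  stopifnot(inherits(fit, "nt_prf_fit"))
  grid <- attr(fit, "grid")
  timeline <- attr(fit, "timeline")
  hrf <- attr(fit, "hrf")
  Y <- average_run_signal(runs)
  basis <- stimulus_basis(timeline, hrf, n_timepoints = nrow(Y))
  lower <- log(c(min(grid$mu), min(grid$sigma)))
  upper <- log(c(max(grid$mu), max(grid$sigma)))
  voxels <- voxels %||% which(fit$valid)

  for (v in voxels) {
    y <- Y[, fit$voxel[v]]
    start <- pmin(pmax(log(c(fit$mu[v], fit$sigma[v])), lower), upper)
    res <- tryCatch(
      optim(start, function(par) -prf_ve_single(y, basis, exp(par[1]), exp(par[2])),
            method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(res)) {
      warn(sprintf("pRF refinement failed for voxel %d; keeping grid fit.",
                   fit$voxel[v]))
      next
    }
    new_ve <- -res$value
    if (new_ve >= fit$ve[v]) {
      mu <- exp(res$par[1]); sigma <- exp(res$par[2])
      p <- as.numeric(basis$C %*%
                        log_gaussian_tuning(basis$levels$numerosity, mu, sigma))
      b <- cor(p, y) * sd(y) / sd(p)
      fit$mu[v] <- mu
      fit$sigma[v] <- sigma
      fit$amplitude[v] <- max(b, 0)
      fit$baseline[v] <- mean(y) - fit$amplitude[v] * mean(p)
      fit$ve[v] <- pmin(pmax(new_ve, 0), 1)
      fit$refined[v] <- TRUE
    }
  }
  fit
}

#' Select the numerosity-tuned populations preferring 1-3
#'
#' Keeps voxels whose fitted preferred numerosity lies in the closed
#' interval `range` and whose variance explained reaches `ve_min` — the
#' pre-selection of populations with preferred response to numerosity 1-3
#' that downstream ROI averaging uses.
#'
#' @param fit An `nt_prf_fit`.
#' @param range Closed preferred-numerosity interval.
#' @param ve_min Minimum variance explained.
#' @return The selected rows of `fit`, with the rule recorded in the
#'   `selection_rule` attribute. An empty selection is valid (with a
#'   warning).
#' @export
select_tuned_voxels <- function(fit, range = c(1, 3), ve_min = 0.3) {
  stopifnot(inherits(fit, "nt_prf_fit"))
  sel <- dplyr::filter(as_tibble(fit), .data$valid,
                       .data$mu >= range[1], .data$mu <= range[2],
                       .data$ve >= ve_min)
  if (nrow(sel) == 0) warn("Tuned-voxel selection is empty.")
  structure(sel, selection_rule = list(range = range, ve_min = ve_min))
}

#' @export
tidy.nt_prf_fit <- function(x, ...) as_tibble(x)

#' @export
glance.nt_prf_fit <- function(x, ...) {
  tibble(n_voxels = nrow(x), n_valid = sum(x$valid),
         median_ve = stats::median(x$ve[x$valid]),
         median_mu = stats::median(x$mu[x$valid]))
}
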