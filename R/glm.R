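#' Block-design GLM design matrix
#'
#' One regressor per stimulus category (the category's 300-ms event train
#' convolved with the HRF, sampled at TR resolution and peak-normalized to
#' 1), plus a constant and a linear drift per run. Multiple runs are
#' combined by stacking the category columns and giving each run its own
#' constant and drift.
#'
#' @param timelines One `nt_timeline` or a list (one per run), all
#'   `category_block` designs.
#' @param hrf [hrf_params()].
#' @param n_timepoints Retained volumes per run (scalar or per-run vector);
#'   defaults to each timeline's implied run shape.
#' @return A matrix of class `nt_design` with named columns; attributes
#'   `categories`, `run_rows` (per-run row counts) and `tr_ms`.
#' @export
build_design_matrix <- function(timelines, hrf = hrf_params(),
                                n_timepoints = NULL) {
  if (inherits(timelines, "nt_timeline")) timelines <- list(timelines)
  if (!length(timelines)) abort("At least one timeline is required.")
  cats <- block_categories()
  n_runs <- length(timelines)
  if (!is.null(n_timepoints)) n_timepoints <- rep_len(n_timepoints, n_runs)

  per_run <- purrr::imap(timelines, function(tl, r) {
    if (nrow(tl) == 0) abort("Empty timeline: cannot build a design matrix.")
    missing <- setdiff(cats, unique(tl$label))
    if (length(missing)) {
      abort(sprintf("Timeline lacks category blocks for: %s.",
                    paste(missing, collapse = ", ")))
    }
    n_t <- if (is.null(n_timepoints)) default_n_timepoints(tl) else n_timepoints[r]
    groups <- purrr::map(cats, ~ which(tl$label == .x))
    X <- event_group_regressors(tl, groups, hrf, n_timepoints = n_t)
    peaks <- apply(X, 2, max)
    if (any(peaks <= 0)) {
      abort(sprintf("Design matrix is rank deficient; empty category columns: %s.",
                    paste(cats[peaks <= 0], collapse = ", ")))
    }
    X <- sweep(X, 2, peaks, "/")  # peak-normalize categories
    colnames(X) <- cats
    X
  })

  rows <- vapply(per_run, nrow, integer(1))
  Xcat <- do.call(rbind, per_run)
  nuisance <- matrix(0, sum(rows), 2 * n_runs)
  nn <- character(2 * n_runs)
  off <- 0L
  for (r in seq_len(n_runs)) {
    idx <- off + seq_len(rows[r])
    nuisance[idx, 2 * r - 1] <- 1
    nuisance[idx, 2 * r] <- seq(-0.5, 0.5, length.out = rows[r])
    nn[2 * r - 1] <- sprintf("constant_run%d", r)
    nn[2 * r] <- sprintf("drift_run%d", r)
    off <- off + rows[r]
  }
  colnames(nuisance) <- nn
  X <- cbind(Xcat, nuisance)

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(sprintf("Design matrix is rank deficient; collinear columns: %s.",
                  paste(dropped, collapse = ", ")))
  }
  structure(X, class = c("nt_design", "matrix", "array"),
            categories = cats, run_rows = rows,
            tr_ms = timeline_tr_ms(timelines[[1]]))
}

#' Fit the block-design GLM
#'
#' Ordinary least squares per voxel. Category betas are additionally
#' rescaled to percent signal change: `100 * beta / b0`, where `b0` is the
#' voxel's mean fitted run constant. No prewhitening is applied by default;
#' `ar_correction = TRUE` inflates contrast variances by the AR(1) factor
#' `(1 + phi_hat) / (1 - phi_hat)` estimated from each voxel's residuals.
#'
#' @param runs One `nt_bold_run` or a list (rows are concatenated in design
#'   order), or a numeric timepoints x voxels matrix.
#' @param design An [build_design_matrix()] result with matching rows.
#' @param ar_correction Apply the AR(1) variance correction?
#' @return A list of class `nt_glm_fit`: `beta` (regressors x voxels),
#'   `psc` (categories x voxels, percent signal), `sigma2`, `dof`,
#'   `xtx_inv`, `flagged` (zero-residual-variance voxels), `ar1_hat`,
#'   `design` metadata.
#' @export
fit_block_glm <- function(runs, design, ar_correction = FALSE) {
  Y <- if (is.matrix(runs)) runs
  else if (inherits(runs, "nt_bold_run")) runs$signal
  else do.call(rbind, purrr::map(runs, "signal"))
  if (nrow(Y) != nrow(design)) {
    abort(sprintf("Run timepoints (%d) do not match design rows (%d).",
                  nrow(Y), nrow(design)))
  }
  X <- unclass(design)
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, Y)
  res <- Y - X %*% beta
  dof <- nrow(X) - qr_x$rank
  sigma2 <- colSums(res^2) / dof
  flagged <- sigma2 <= 1e-12 * pmax(colMeans(Y^2), 1e-300)

  cats <- attr(design, "categories")
  const_idx <- grep("^constant_run", colnames(X))
  b0 <- colMeans(beta[const_idx, , drop = FALSE])
  psc <- 100 * sweep(beta[cats, , drop = FALSE], 2, b0, "/")

  ar1_hat <- NULL
  if (ar_correction) {
    n_t <- nrow(res)
    ar1_hat <- colSums(res[-1, , drop = FALSE] * res[-n_t, , drop = FALSE]) /
      pmax(colSums(res^2), 1e-300)
    ar1_hat <- pmin(pmax(ar1_hat, -0.99), 0.99)
  }

  structure(list(beta = beta, psc = psc, sigma2 = sigma2, dof = dof,
                 xtx_inv = chol2inv(qr.R(qr_x)),
                 regressors = colnames(X), categories = cats,
                 flagged = flagged, ar1_hat = ar1_hat,
                 voxels = if (inherits(runs, "list")) runs[[1]]$voxels
                          else if (inherits(runs, "nt_bold_run")) runs$voxels
                          else NULL),
            class = "nt_glm_fit")
}

#' Contrast weights for one category against rest
#'
#' @param fit An `nt_glm_fit`.
#' @param category Category name receiving weight 1; all other regressors 0
#'   (rest is the implicit baseline).
#' @return Named numeric vector over the fit's regressors.
#' @export
contrast_vs_rest <- function(fit, category = "scenery") {
  w <- stats::setNames(numeric(length(fit$regressors)), fit$regressors)
  if (!category %in% names(w)) {
    abort(sprintf("Unknown regressor '%s'.", category))
  }
  w[category] <- 1
  w
}

#' Per-voxel contrast t statistic
#'
#' `t = c'beta / sqrt(sigma2 * c' (X'X)^-1 c)`. Voxels flagged at fit time
#' (zero residual variance) propagate as `NA`.
#'
#' @param fit An `nt_glm_fit`.
#' @param contrast Numeric weight vector over the regressors (or a named
#'   vector covering a subset; missing regressors get weight 0).
#' @return A tibble with `voxel` and `t`.
#' @export
t_contrast <- function(fit, contrast) {
  w <- stats::setNames(numeric(length(fit$regressors)), fit$regressors)
  if (!is.null(names(contrast))) {
    bad <- setdiff(names(contrast), fit$regressors)
    if (length(bad)) abort(sprintf("Unknown regressors in contrast: %s.",
                                   paste(bad, collapse = ", ")))
    w[names(contrast)] <- contrast
  } else {
    if (length(contrast) != length(w)) {
      abort("Unnamed contrast must have one weight per regressor.")
    }
    w[] <- contrast
  }
  if (all(w == 0)) abort("Contrast weights are all zero.")
  eff <- as.numeric(crossprod(w, fit$beta))
  var_c <- as.numeric(t(w) %*% fit$xtx_inv %*% w)
  se2 <- fit$sigma2 * var_c
  if (!is.null(fit$ar1_hat)) {
    se2 <- se2 * (1 + fit$ar1_hat) / (1 - fit$ar1_hat)
  }
  t <- eff / sqrt(se2)
  t[fit$flagged] <- NA_real_
  tibble(voxel = seq_along(t), t = t)
}

#' Scenery-based voxel inclusion mask
#'
#' Retains voxels whose scenery-versus-rest t statistic is at least the
#' threshold; voxels with `t < threshold` (negative or non-significant
#' scenery responses) are excluded from downstream ROI averaging. A voxel at
#' exactly the threshold is retained.
#'
#' @param t_values Tibble from [t_contrast()] (or numeric vector of t).
#' @param threshold Exclusion threshold (default 1.96).
#' @return Logical inclusion vector with attribute `n_excluded`; `NA` t
#'   values are excluded.
#' @export
scenery_mask <- function(t_values, threshold = 1.96) {
  t <- if (is.data.frame(t_values)) t_values$t else t_values
  keep <- !is.na(t) & t >= threshold
  if (!any(keep)) warn("Scenery mask is empty: every voxel excluded.")
  structure(keep, n_excluded = sum(!keep), threshold = threshold)
}

#' @export
tidy.nt_glm_fit <- function(x, ...) {
  n_cat <- nrow(x$psc)
  n_vox <- ncol(x$psc)
  out <- tibble(
    voxel = rep(seq_len(n_vox), each = n_cat),
    category = rep(rownames(x$psc), times = n_vox),
    psc = as.numeric(x$psc),
    flagged = rep(x$flagged, each = n_cat)
  )
  if (!is.null(x$voxels)) {
    meta <- dplyr::mutate(dplyr::select(x$voxels, dplyr::any_of(
      c("subject", "roi", "kind"))), voxel = dplyr::row_number())
    out <- dplyr::left_join(out, meta, by = "voxel")
  }
  out
}

#' @export
glance.nt_glm_fit <- function(x, ...) {
  tibble(n_voxels = ncol(x$beta), n_regressors = nrow(x$beta),
         dof = x$dof, n_flagged = sum(x$flagged))
}
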