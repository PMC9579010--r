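#' Full-pipeline configuration
#'
#' Bundles every stage's settings: cohort simulation, stimulus pools, the
#' pRF search grid, and the inference thresholds (scenery-exclusion t,
#' minimum variance explained, selection range, FDR level).
#'
#' @param seed Default master seed for [run_pipeline()].
#' @param cohort A [cohort_config()].
#' @param pool A [pool_spec()].
#' @param grid A [prf_grid()].
#' @param scenery_t Scenery-versus-rest exclusion threshold.
#' @param ve_min Minimum pRF variance explained for tuned selection.
#' @param select_range Closed preferred-numerosity selection interval.
#' @param alpha FDR level for all test families.
#' @param refine Run continuous pRF refinement after the grid stage?
#' @param apply_scenery_mask Use the scenery mask in the headline ROI table
#'   (the unmasked parallel is always produced too)?
#' @return A list of class `numerotune_config`.
#' @export
numerotune_config <- function(seed = 1, cohort = cohort_config(),
                              pool = pool_spec(), grid = prf_grid(),
                              scenery_t = 1.96, ve_min = 0.3,
                              select_range = c(1, 3), alpha = 0.05,
                              refine = FALSE, apply_scenery_mask = TRUE) {
  structure(as.list(environment()), class = "numerotune_config")
}

#' Validate a pipeline configuration
#'
#' Fills nothing in (the constructor owns defaults) but checks cross-field
#' constraints and aggregates every violation into one error.
#'
#' @param config A [numerotune_config()].
#' @return The config, invisibly, if valid; otherwise an error listing all
#'   problems.
#' @export
validate_config <- function(config) {
  errs <- character()
  push <- function(msg) errs <<- c(errs, msg)
  ch <- config$cohort
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1) {
    push("`alpha` must lie in (0, 1).")
  }
  if (!is.numeric(config$ve_min) || config$ve_min < 0 || config$ve_min >= 1) {
    push("`ve_min` must lie in [0, 1).")
  }
  if (length(config$select_range) != 2 || any(config$select_range <= 0) ||
      diff(config$select_range) < 0) {
    push("`select_range` must be an increasing pair of positive numerosities.")
  }
  if (!is.numeric(config$scenery_t) || !is.finite(config$scenery_t)) {
    push("`scenery_t` must be a finite number.")
  }
  if (ch$tr_ms <= 0) push("`tr_ms` must be positive.")
  if (ch$n_subjects < 1) push("Cohort needs at least one subject.")
  if (ch$nf_subjects > ch$n_subjects) {
    push("`nf_subjects` cannot exceed `n_subjects`.")
  }
  if (ch$voxels_per_roi < 1) push("`voxels_per_roi` must be at least 1.")
  if (ch$noise_sd < 0) push("`noise_sd` must be non-negative.")
  if (abs(ch$ar1) >= 1) push("`ar1` must lie in (-1, 1).")
  pool_sizes <- c(
    nat_low = config$pool$n_one + config$pool$n_two + config$pool$n_three,
    nat_high = config$pool$n_high, scenery = config$pool$n_scenery,
    dot_low = config$pool$n_dot_low, dot_20 = config$pool$n_dot_20,
    dot_high = config$pool$n_dot_high)
  small <- names(pool_sizes)[pool_sizes < 30]
  if (length(small)) {
    push(sprintf("Block pools need at least 30 items; too small: %s.",
                 paste(small, collapse = ", ")))
  }
  if (length(errs)) {
    abort(paste(c("Invalid configuration:",
                  paste0("  - ", errs)), collapse = "\n"))
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort, fits pRFs to the localizer runs and selects the
#' populations tuned to the configured numerosity range, fits the
#' block-design GLM, applies the scenery exclusion, builds the masked and
#' unmasked ROI response tables, and runs the nonparametric test families
#' (positive responses per ROI x category, and the low-versus-high
#' numerosity comparison across maps). Deterministic given the seed.
#'
#' @param config A validated [numerotune_config()].
#' @param master_seed Master seed (defaults to `config$seed`).
#' @return A list of class `nt_report`: `config_hash`, `seed`,
#'   `selection_counts`, `mask_counts`, `roi_table`, `roi_table_unmasked`,
#'   `tests` (list: `positivity_maps`, `positivity_controls`,
#'   `low_vs_high`, `low_vs_high_unmasked`), `prf_fits`, `ground_truth`.
#' @export
run_pipeline <- function(config = numerotune_config(),
                         master_seed = config$seed) {
  validate_config(config)
  cohort <- simulate_cohort(config$cohort, master_seed, config$pool)

  psc_long <- vector("list", length(cohort$subjects))
  prf_fits <- vector("list", length(cohort$subjects))
  sel_counts <- mask_counts <- vector("list", length(cohort$subjects))

  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    fit <- fit_prf_grid(sub$localizer_runs, grid = config$grid)
    if (config$refine) fit <- refine_prf_fit(fit, sub$localizer_runs)
    sel <- suppressWarnings(
      select_tuned_voxels(fit, config$select_range, config$ve_min))
    prf_fits[[i]] <- fit

    design <- build_design_matrix(
      purrr::map(sub$block_runs, "timeline"),
      n_timepoints = vapply(sub$block_runs, function(r) as.integer(r$n_retained),
                            integer(1)))
    glm <- fit_block_glm(sub$block_runs, design)
    tsc <- t_contrast(glm, contrast_vs_rest(glm, "scenery"))
    mask <- suppressWarnings(scenery_mask(tsc, config$scenery_t))

    long <- tidy(glm)
    long$selected <- long$voxel %in% sel$voxel
    long$mask_pass <- mask[long$voxel]
    psc_long[[i]] <- long

    sel_counts[[i]] <- tibble(subject = sub$subject,
                              n_selected = nrow(sel),
                              n_voxels = nrow(fit))
    mask_counts[[i]] <- tibble(subject = sub$subject,
                               n_excluded = attr(mask, "n_excluded"),
                               n_selected_masked = sum(sel$voxel %in%
                                                         which(mask)))
  }

  psc_long <- dplyr::bind_rows(psc_long)
  roi_masked <- roi_response_table(psc_long,
                                   apply_scenery_mask = config$apply_scenery_mask)
  roi_unmasked <- roi_response_table(psc_long, apply_scenery_mask = FALSE)

  maps_present <- intersect(numerosity_maps(), unique(psc_long$roi))
  tests <- list(
    positivity_maps = test_positive_response(roi_masked, rois = maps_present,
                                             alpha = config$alpha),
    positivity_controls = test_positive_response(roi_masked,
                                                 rois = control_rois(),
                                                 alpha = config$alpha),
    low_vs_high = test_low_vs_high(roi_masked, alpha = config$alpha),
    low_vs_high_unmasked = test_low_vs_high(roi_unmasked,
                                            alpha = config$alpha)
  )

  structure(list(
    config = config, config_hash = rlang::hash(config), seed = master_seed,
    selection_counts = dplyr::bind_rows(sel_counts),
    mask_counts = dplyr::bind_rows(mask_counts),
    roi_table = roi_masked, roi_table_unmasked = roi_unmasked,
    tests = tests, prf_fits = prf_fits,
    ground_truth = cohort$ground_truth
  ), class = "nt_report")
}

#' @export
print.nt_report <- function(x, ...) {
  cat("numerotune pipeline report\n")
  cat(sprintf("  seed %s, config %s\n", x$seed, substr(x$config_hash, 1, 8)))
  cat(sprintf("  subjects: %d; voxels/subject: %d; selected tuned voxels: %s\n",
              nrow(x$selection_counts),
              x$selection_counts$n_voxels[1],
              paste(x$selection_counts$n_selected, collapse = "/")))
  cat(sprintf("  scenery exclusions per subject: %s\n",
              paste(x$mask_counts$n_excluded, collapse = "/")))
  lvh <- dplyr::filter(x$tests$low_vs_high,
                       .data$comparison == "natural low > high")
  cat("  low vs high numerosity (natural images), per map:\n")
  for (i in seq_len(nrow(lvh))) {
    cat(sprintf("    %-5s n=%d  p=%.4g  p_adj=%.4g %s\n",
                lvh$roi[i], lvh$n[i], lvh$p_value[i], lvh$p_adjusted[i],
                ifelse(isTRUE(lvh$significant[i]), "*", "")))
  }
  invisible(x)
}
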