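#' Cohort simulation configuration
#'
#' Ground-truth composition of the synthetic cohort: seven subjects, each
#' with six numerosity-map ROIs (NPC1-3, NTO, NPO, NF; NF present in only
#' four subjects) and three control ROIs (V1, LO, PPA). Numerosity maps mix
#' 50% numerosity-tuned, 20% scenery-responsive, 20% untuned-visual and 10%
#' null voxels; V1/LO are mostly untuned-visual and PPA mostly
#' scenery-responsive. Tuned voxels draw preferred numerosity log-uniformly
#' on `mu_range` with width increasing linearly with preferred numerosity.
#'
#' @param n_subjects Number of subjects.
#' @param voxels_per_roi Voxels simulated per ROI.
#' @param nf_subjects How many subjects have a frontal (NF) map.
#' @param n_localizer_runs,n_block_runs Runs per subject per experiment.
#' @param tr_ms Repetition time, ms.
#' @param n_discard Leading volumes discarded from each acquired run.
#' @param n_post_trs Trailing rest volumes appended after the task (the
#'   default run shape acquires 256 volumes and retains 248).
#' @param noise_sd Marginal temporal SD of voxel noise, percent signal.
#' @param ar1 Lag-1 autocorrelation of the noise.
#' @param drift_max Max absolute linear drift per run, percent signal.
#' @param amp_tuned,amp_untuned,amp_scenery Median response amplitudes
#'   (percent signal) per voxel kind; each voxel draws log-normally around
#'   its median with `amp_sdlog`.
#' @param amp_sdlog Log-SD of per-voxel amplitude draws.
#' @param scenery_gain_range Tuned voxels' scenery response as a uniform
#'   multiple of their own amplitude.
#' @param mu_range Range of tuned preferred numerosities (log-uniform).
#' @param sigma_intercept,sigma_slope,sigma_jitter Tuning width model:
#'   `sigma = intercept + slope * mu + N(0, jitter)`, floored at 0.1.
#' @param tuned_kind Set to `"visual_untuned"` to build the untuned control
#'   cohort (tuned voxels replaced by untuned-visual ones).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 7, voxels_per_roi = 200,
                          nf_subjects = 4, n_localizer_runs = 4,
                          n_block_runs = 7, tr_ms = 1500, n_discard = 8,
                          n_post_trs = 8, noise_sd = 1.0, ar1 = 0.3,
                          drift_max = 0.5, amp_tuned = 5.0,
                          amp_untuned = 1.0, amp_scenery = 1.5,
                          amp_sdlog = 0.25,
                          scenery_gain_range = c(0, 0.5),
                          mu_range = c(1, 7), sigma_intercept = 0.25,
                          sigma_slope = 0.1, sigma_jitter = 0.05,
                          tuned_kind = "numerosity_tuned") {
  structure(as.list(environment()), class = "cohort_config")
}

numerosity_maps <- function() c("NPC1", "NPC2", "NPC3", "NTO", "NPO", "NF")
control_rois <- function() c("V1", "LO", "PPA")

roi_mix <- function(roi) {
  if (roi %in% numerosity_maps()) {
    c(numerosity_tuned = 0.5, scenery_responsive = 0.2,
      visual_untuned = 0.2, null = 0.1)
  } else if (roi == "PPA") {
    c(scenery_responsive = 0.8, visual_untuned = 0.1, null = 0.1)
  } else {
    c(visual_untuned = 0.8, scenery_responsive = 0.1, null = 0.1)
  }
}

# Ground-truth voxel specs for one subject.
make_voxel_specs <- function(config, subject, seed) {
  rois <- c(numerosity_maps(), control_rois())
  if (subject > config$nf_subjects) rois <- setdiff(rois, "NF")
  with_seed(seed, {
    purrr::map_dfr(rois, function(roi) {
      mix <- roi_mix(roi)
      counts <- diff(round(cumsum(c(0, mix)) * config$voxels_per_roi))
      kind <- rep(names(mix), counts)
      if (config$tuned_kind != "numerosity_tuned") {
        kind[kind == "numerosity_tuned"] <- config$tuned_kind
      }
      nv <- length(kind)
      mu <- sigma <- scenery_gain <- rep(NA_real_, nv)
      amplitude <- numeric(nv)
      tuned <- kind == "numerosity_tuned"
      mu[tuned] <- exp(runif(sum(tuned), log(config$mu_range[1]),
                             log(config$mu_range[2])))
      sigma[tuned] <- pmax(0.1, config$sigma_intercept +
                             config$sigma_slope * mu[tuned] +
                             rnorm(sum(tuned), 0, config$sigma_jitter))
      med <- c(numerosity_tuned = config$amp_tuned,
               scenery_responsive = config$amp_scenery,
               visual_untuned = config$amp_untuned, null = 0)
      amplitude <- ifelse(kind == "null", 0,
                          stats::rlnorm(nv, log(pmax(med[kind], 1e-12)),
                                        config$amp_sdlog))
      scenery_gain[tuned] <- amplitude[tuned] *
        runif(sum(tuned), config$scenery_gain_range[1],
              config$scenery_gain_range[2])
      tibble(subject = subject, roi = roi, voxel = seq_len(nv), kind = kind,
             mu = mu, sigma = sigma, amplitude = amplitude,
             scenery_gain = scenery_gain,
             noise_sd = config$noise_sd, ar1 = config$ar1,
             drift = runif(nv, -config$drift_max, config$drift_max))
    })
  })
}

# AR(1) noise with *marginal* SD `sd` (innovation SD = sd * sqrt(1 - phi^2));
# `sd` and `phi` may be per-voxel vectors. One column per voxel.
ar1_noise <- function(n_t, n_v, sd, phi) {
  sd <- rep_len(sd, n_v)
  phi <- rep_len(phi, n_v)
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- matrix(rnorm(n_t * n_v), n_t, n_v) * rep(innov_sd, each = n_t)
  if (any(phi != 0)) {
    e[1, ] <- rnorm(n_v, 0, sd)  # stationary start
    for (t in 2:n_t) e[t, ] <- phi * e[t - 1, ] + e[t, ]
  }
  e
}

#' Simulate one BOLD run
#'
#' Builds each voxel's noiseless percent-signal prediction through the
#' shared forward model (event train, HRF convolution, TR averaging), adds
#' AR(1) noise and a per-voxel linear drift on a baseline of 100 arbitrary
#' units, simulates `n_discard` pre-task dummy volumes, and discards them.
#'
#' @param voxels Ground-truth voxel tibble (see [make_voxel_specs()] fields).
#' @param timeline The run's `nt_timeline`.
#' @param seed Integer seed; identical seeds give bitwise-identical runs.
#' @param hrf [hrf_params()].
#' @param n_discard Discarded leading volumes.
#' @param n_post_trs Trailing rest volumes.
#' @param baseline Baseline signal level, arbitrary units.
#' @param noiseless Set `TRUE` to skip noise and drift entirely.
#' @return A list of class `nt_bold_run`: `signal` (retained timepoints x
#'   voxels matrix), `tr_ms`, `n_discarded`, `n_retained`, `voxels`,
#'   `timeline`, `subject`, `seed`.
#' @export
simulate_bold_run <- function(voxels, timeline, seed = 1, hrf = hrf_params(),
                              n_discard = 8, n_post_trs = 8, baseline = 100,
                              noiseless = FALSE) {
  tr_ms <- timeline_tr_ms(timeline)
  if (timeline_duration_ms(timeline) < 9 * tr_ms) {
    abort("Timeline spans fewer than 9 TRs; too short to simulate a run.")
  }
  n_retained <- default_n_timepoints(timeline, n_post_trs)
  n_acq <- n_retained + n_discard

  basis <- stimulus_basis(timeline, hrf, n_timepoints = n_retained)
  W <- vapply(seq_len(nrow(voxels)), function(i) {
    level_amplitudes(basis$levels, voxels$kind[i], voxels$mu[i],
                     voxels$sigma[i], voxels$amplitude[i],
                     voxels$scenery_gain[i])
  }, numeric(nrow(basis$levels)))
  if (is.null(dim(W))) W <- matrix(W, nrow = nrow(basis$levels))
  psc <- basis$C %*% W  # retained timepoints x voxels

  n_v <- nrow(voxels)
  if (noiseless) {
    full <- rbind(matrix(0, n_discard, n_v), psc)
    signal <- baseline * (1 + full / 100)
  } else {
    signal <- with_seed(seed, {
      noise <- ar1_noise(n_acq, n_v, voxels$noise_sd, voxels$ar1)
      t_frac <- (seq_len(n_acq) - 1) / max(n_acq - 1, 1)
      drift <- outer(t_frac, voxels$drift)
      full_psc <- rbind(matrix(0, n_discard, n_v), psc) + drift
      baseline * (1 + full_psc / 100) + noise * baseline / 100
    })
  }
  structure(list(signal = signal[(n_discard + 1):n_acq, , drop = FALSE],
                 tr_ms = tr_ms, n_discarded = n_discard,
                 n_retained = n_retained, voxels = voxels,
                 timeline = timeline, subject = voxels$subject[1],
                 seed = seed),
            class = "nt_bold_run")
}

#' Simulate a multi-subject cohort
#'
#' Generates the stimulus pools, per-run timelines and BOLD runs for a full
#' synthetic cohort: per subject, `n_localizer_runs` numerosity-sweep runs
#' and `n_block_runs` six-category block runs, with ground truth recorded
#' beside the signals.
#'
#' @param config A [cohort_config()].
#' @param master_seed Integer master seed; all randomness derives from it.
#' @param pool A [pool_spec()] for the block-design stimulus pools.
#' @return A list of class `nt_cohort`: `subjects` (per subject: `voxels`,
#'   `localizer_runs`, `block_runs`), `manifest`, `ground_truth` (all voxel
#'   specs), `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), master_seed = 1,
                            pool = pool_spec()) {
  seeds <- derive_seeds(master_seed, 2 + config$n_subjects, salt = 1L)
  manifest <- build_pool_manifest(pool, seed = seeds[1])

  subjects <- purrr::map(seq_len(config$n_subjects), function(s) {
    s_seeds <- derive_seeds(seeds[2 + s], 2 +
                              config$n_localizer_runs + config$n_block_runs)
    voxels <- make_voxel_specs(config, s, s_seeds[1])
    localizer_runs <- purrr::map(seq_len(config$n_localizer_runs), function(r) {
      tl <- build_localizer_timeline(tr_ms = config$tr_ms,
                                     seed = s_seeds[2 + r])
      simulate_bold_run(voxels, tl, seed = s_seeds[2 + r],
                        n_discard = config$n_discard,
                        n_post_trs = config$n_post_trs)
    })
    block_runs <- purrr::map(seq_len(config$n_block_runs), function(r) {
      rs <- s_seeds[2 + config$n_localizer_runs + r]
      tl <- build_block_timeline(manifest, tr_ms = config$tr_ms, seed = rs)
      simulate_bold_run(voxels, tl, seed = rs,
                        n_discard = config$n_discard,
                        n_post_trs = config$n_post_trs)
    })
    list(subject = s, voxels = voxels, localizer_runs = localizer_runs,
         block_runs = block_runs)
  })

  structure(list(subjects = subjects, manifest = manifest,
                 ground_truth = purrr::map_dfr(subjects, "voxels"),
                 config = config, seed = master_seed),
            class = "nt_cohort")
}

#' Write a cohort's tabular artifacts to disk
#'
#' Writes the ground-truth voxel table, the pool manifest and every run's
#' events TSV (BIDS-style). Signal matrices stay in memory; pass
#' `write_signals = TRUE` to also write them as TSV.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param out_dir Output directory.
#' @param write_signals Also write voxel x time signal tables?
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, write_signals = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$ground_truth, file.path(out_dir, "ground_truth.tsv"))
  readr::write_tsv(as_tibble(cohort$manifest), file.path(out_dir, "pool_manifest.tsv"))
  for (sub in cohort$subjects) {
    sdir <- file.path(out_dir, sprintf("sub-%02d", sub$subject))
    dir.create(sdir, showWarnings = FALSE)
    runs <- c(sub$localizer_runs, sub$block_runs)
    names <- c(sprintf("localizer_run-%02d", seq_along(sub$localizer_runs)),
               sprintf("blocks_run-%02d", seq_along(sub$block_runs)))
    for (i in seq_along(runs)) {
      write_events_tsv(runs[[i]]$timeline,
                       file.path(sdir, paste0(names[i], "_events.tsv")))
      if (write_signals) {
        readr::write_tsv(as_tibble(as.data.frame(runs[[i]]$signal)),
                         file.path(sdir, paste0(names[i], "_bold.tsv")),
                         col_names = FALSE)
      }
    }
  }
  invisible(out_dir)
}
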