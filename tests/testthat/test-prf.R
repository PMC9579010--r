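test_that("prediction peaks within the preferred-numerosity epochs", {
  tl <- build_localizer_timeline(seed = 1)
  p <- predict_prf_timecourse(tl, 2, 0.4)
  peak_t_ms <- (which.max(p) - 1) * 1500
  # numerosity-2 epochs are the 2nd ascending and 2nd-to-last descending
  # epoch of each 101400-ms pass
  starts <- as.vector(outer(c(1, 18) * 3900, 0:3 * 101400, "+"))
  lag_ok <- any(peak_t_ms >= starts & peak_t_ms <= starts + 3900 + 9000)
  expect_true(lag_ok)
  expect_error(predict_prf_timecourse(tl, 2, 0), "sigma")
  expect_error(predict_prf_timecourse(tl, -1, 0.4), "mu")
})

test_that("a very wide pRF approaches the untuned visual response", {
  tl <- build_localizer_timeline(seed = 1)
  wide <- predict_prf_timecourse(tl, 2, 50)
  basis <- numerotune:::stimulus_basis(tl)
  untuned <- as.numeric(basis$C %*% rep(1, nrow(basis$levels)))
  expect_gt(cor(wide, untuned), 0.999)
})

test_that("grid fit recovers noiseless tuning within one grid step", {
  tl <- build_localizer_timeline(seed = 1)
  g <- prf_grid()
  vox <- tibble::tibble(subject = 1, roi = "NPC1", voxel = 1:3,
                        kind = "numerosity_tuned",
                        mu = c(2, 3.5, g$mu[8]),
                        sigma = c(0.4, 0.6, g$sigma[10]), amplitude = 2,
                        scenery_gain = 0, noise_sd = 0, ar1 = 0, drift = 0)
  run <- simulate_bold_run(vox, tl, noiseless = TRUE)
  fit <- fit_prf_grid(run)
  grid_step <- exp(log(10) / 24)  # ratio between adjacent mu grid points
  expect_true(all(abs(log(fit$mu / vox$mu)) <= log(grid_step) + 1e-9))
  expect_true(all(fit$ve > 0.99))
  # on-grid ground truth is recovered exactly, with essentially perfect VE
  expect_equal(fit$mu[3], g$mu[8])
  expect_equal(fit$sigma[3], g$sigma[10])
  expect_gt(fit$ve[3], 0.999)
})

test_that("pure-noise voxels fit with low variance explained", {
  tl <- build_localizer_timeline(seed = 1)
  vox <- tibble::tibble(subject = 1, roi = "NPC1", voxel = 1:100,
                        kind = "null", mu = NA, sigma = NA, amplitude = 0,
                        scenery_gain = NA, noise_sd = 1, ar1 = 0.3, drift = 0)
  run <- simulate_bold_run(vox, tl, seed = 50)
  fit <- fit_prf_grid(run)
  expect_lt(median(fit$ve), 0.1)
})

test_that("untuned visual voxels drift to the widest grid sigma", {
  tl <- build_localizer_timeline(seed = 1)
  vox <- tibble::tibble(subject = 1, roi = "V1", voxel = 1:20,
                        kind = "visual_untuned", mu = NA, sigma = NA,
                        amplitude = 3, scenery_gain = NA, noise_sd = 0.3,
                        ar1 = 0, drift = 0)
  run <- simulate_bold_run(vox, tl, seed = 51)
  fit <- fit_prf_grid(run)
  g <- prf_grid()
  expect_gt(median(fit$sigma), g$sigma[15])
})

test_that("grid argmax matches exhaustive enumeration on a small grid", {
  tl <- build_localizer_timeline(seed = 1)
  small <- prf_grid(mu_range = c(1.5, 6), n_mu = 3,
                    sigma_range = c(0.2, 1), n_sigma = 3)
  vox <- tibble::tibble(subject = 1, roi = "NPC1", voxel = 1:5,
                        kind = "numerosity_tuned",
                        mu = c(1.6, 2.5, 4, 5.5, 3),
                        sigma = c(0.3, 0.5, 0.8, 0.4, 0.6), amplitude = 2,
                        scenery_gain = 0, noise_sd = 0.8, ar1 = 0, drift = 0)
  run <- simulate_bold_run(vox, tl, seed = 52)
  fit <- fit_prf_grid(run, grid = small)
  for (v in 1:5) {
    y <- run$signal[, v]
    best <- c(ve = -Inf, mu = NA, sigma = NA)
    for (i in seq_len(nrow(small$pairs))) {
      p <- predict_prf_timecourse(tl, small$pairs$mu[i], small$pairs$sigma[i],
                                  n_timepoints = length(y))
      ols <- stats::lm(y ~ p)
      ve <- if (stats::coef(ols)[2] <= 0) 0 else summary(ols)$r.squared
      if (ve > best["ve"]) {
        best <- c(ve = ve, mu = small$pairs$mu[i], sigma = small$pairs$sigma[i])
      }
    }
    expect_equal(fit$mu[v], unname(best["mu"]))
    expect_equal(fit$sigma[v], unname(best["sigma"]))
    expect_equal(fit$ve[v], unname(best["ve"]), tolerance = 1e-8)
  }
})

test_that("refinement improves VE monotonically and sharpens noiseless fits", {
  tl <- build_localizer_timeline(seed = 1)
  vox <- tibble::tibble(subject = 1, roi = "NPC1", voxel = 1:3,
                        kind = "numerosity_tuned", mu = c(2.17, 1.41, 3.9),
                        sigma = c(0.37, 0.52, 0.71), amplitude = 2,
                        scenery_gain = 0, noise_sd = c(0, 0.5, 0.5),
                        ar1 = 0, drift = 0)
  run <- simulate_bold_run(vox, tl, seed = 53)
  run$signal[, 1] <- simulate_bold_run(vox[1, ], tl, noiseless = TRUE)$signal
  coarse <- fit_prf_grid(run)
  refined <- refine_prf_fit(coarse, run)
  expect_true(all(refined$ve >= coarse$ve - 1e-12))
  expect_equal(refined$mu[1], 2.17, tolerance = 1e-3)
  g <- prf_grid()
  expect_true(all(refined$mu >= min(g$mu) - 1e-9 &
                    refined$mu <= max(g$mu) + 1e-9))
  expect_true(all(refined$sigma >= min(g$sigma) - 1e-9 &
                    refined$sigma <= max(g$sigma) + 1e-9))
})

test_that("constant voxel series are flagged invalid with zero VE", {
  tl <- build_localizer_timeline(seed = 1)
  vox <- tibble::tibble(subject = 1, roi = "NPC1", voxel = 1,
                        kind = "null", mu = NA, sigma = NA, amplitude = 0,
                        scenery_gain = NA, noise_sd = 0, ar1 = 0, drift = 0)
  run <- simulate_bold_run(vox, tl, noiseless = TRUE)
  fit <- fit_prf_grid(run)
  expect_false(fit$valid[1])
  expect_equal(fit$ve[1], 0)
})

test_that("tuned selection applies the preferred-range and VE rule", {
  fit <- structure(
    tibble::tibble(voxel = 1:4, mu = c(2, 5, 2, 3), sigma = 0.5,
                   amplitude = 1, baseline = 100,
                   ve = c(0.5, 0.9, 0.1, 0.31), valid = TRUE,
                   refined = FALSE),
    class = c("nt_prf_fit", class(tibble::tibble())))
  sel <- select_tuned_voxels(fit, range = c(1, 3), ve_min = 0.3)
  expect_equal(sel$voxel, c(1L, 4L))
  rule <- attr(sel, "selection_rule")
  expect_equal(rule$range, c(1, 3))
  expect_warning(select_tuned_voxels(fit, range = c(1, 3), ve_min = 0.99),
                 "empty")
})
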