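block_design_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tl <- build_block_timeline(shared_manifest(), seed = 21)
      cache <<- list(tl = tl, X = build_design_matrix(tl))
    }
    cache
  }
})

test_that("single-run design has six category and two nuisance columns", {
  fx <- block_design_fixture()
  X <- fx$X
  expect_equal(colnames(X), c(block_categories(), "constant_run1",
                              "drift_run1"))
  expect_equal(nrow(X), 248)
  expect_equal(unname(apply(X[, block_categories()], 2, max)), rep(1, 6))
  # a category regressor is nonzero only near its own two blocks
  tl <- fx$tl
  for (cat in c("scenery", "dot_20")) {
    blocks <- range(tl$onset_ms[tl$label == cat]) / 1500
    active <- which(X[, cat] > 0.05)
    expect_true(all(active >= blocks[1] - 1 & active <= blocks[2] + 12))
  }
})

test_that("multi-run designs stack categories with per-run nuisance", {
  tls <- lapply(1:2, function(i) build_block_timeline(shared_manifest(),
                                                      seed = i))
  X <- build_design_matrix(tls, n_timepoints = c(248, 248))
  expect_equal(ncol(X), 6 + 4)
  expect_equal(nrow(X), 496)
  expect_equal(sum(X[1:248, "constant_run2"]), 0)
  expect_equal(sum(X[249:496, "constant_run1"]), 0)
})

test_that("degenerate designs are rejected with informative errors", {
  empty <- build_localizer_timeline(seed = 1)  # lacks category labels
  expect_error(build_design_matrix(empty), "lacks category")
  fx <- block_design_fixture()
  expect_error(build_design_matrix(fx$tl, n_timepoints = 5),
               "rank deficient")
})

test_that("OLS betas match hand-computed normal equations on a toy system", {
  set.seed(42)
  X <- cbind(a = rnorm(10), constant_run1 = 1, drift_run1 = seq(-0.5, 0.5,
                                                                length.out = 10))
  X <- structure(X, class = c("nt_design", "matrix", "array"),
                 categories = "a", run_rows = 10L, tr_ms = 1500)
  Y <- matrix(rnorm(20), 10, 2)
  fit <- fit_block_glm(Y, X)
  beta_hand <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unclass(fit$beta), unclass(beta_hand), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$dof, 7)
})

test_that("noiseless runs recover ground-truth betas and percent signal", {
  fx <- block_design_fixture()
  X <- fx$X
  b_true <- rbind(matrix(c(1.2, 0.4, 0.8, 0.3, 0.2, 0.1,
                           0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 6, 2),
                  constant = c(100, 200), drift = c(0.5, -0.3))
  Y <- unclass(X) %*% b_true
  fit <- fit_block_glm(Y, X)
  expect_equal(unname(fit$beta), unname(b_true), tolerance = 1e-6)
  expect_equal(unname(fit$psc[, 1]),
               unname(100 * b_true[1:6, 1] / 100), tolerance = 1e-6)
  expect_equal(unname(fit$psc[, 2]),
               unname(100 * b_true[1:6, 2] / 200), tolerance = 1e-6)
  expect_true(all(fit$flagged))  # zero residual variance is flagged
})

test_that("percent-signal betas are invariant to run scaling, linear in signal", {
  fx <- block_design_fixture()
  X <- fx$X
  set.seed(7)
  Y <- unclass(X) %*% matrix(c(1, 0.5, 0.8, 0.2, 0.3, 0.1, 100, 0.2), 8, 1) +
    rnorm(248, 0, 0.5)
  f1 <- fit_block_glm(Y, X)
  f3 <- fit_block_glm(3 * Y, X)
  expect_equal(f1$psc, f3$psc, tolerance = 1e-10)
  # doubling the deviation from baseline doubles category betas
  const_fit <- f1$beta["constant_run1", 1]
  Y2 <- 2 * (Y - const_fit) + const_fit
  f2 <- fit_block_glm(Y2, X)
  expect_equal(unname(f2$beta[1:6, 1]), unname(2 * f1$beta[1:6, 1]),
               tolerance = 1e-8)
})

test_that("contrast t flips sign with its weights and rejects empty weights", {
  fx <- block_design_fixture()
  set.seed(8)
  Y <- matrix(100 + rnorm(248 * 5), 248, 5) + unclass(fx$X)[, "scenery"] %o%
    c(0, 0.5, 1, 2, 4)
  fit <- fit_block_glm(Y, fx$X)
  t_pos <- t_contrast(fit, contrast_vs_rest(fit, "scenery"))
  w <- contrast_vs_rest(fit, "scenery")
  t_neg <- t_contrast(fit, -w)
  expect_equal(t_neg$t, -t_pos$t)
  expect_error(t_contrast(fit, w - w), "all zero")
  expect_error(t_contrast(fit, stats::setNames(1, "no_such")), "Unknown")
  expect_true(all(diff(t_pos$t[2:5]) > 0))
})

test_that("scenery mask keeps t at threshold and excludes below it", {
  mask <- scenery_mask(c(1.96, 1.95, 2.5, NA, -3), threshold = 1.96)
  expect_equal(as.logical(mask), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(attr(mask, "n_excluded"), 3)
  expect_warning(scenery_mask(c(0.5, 1.0)), "empty")
})

test_that("white-noise null calibration sits at the Gaussian tail rate", {
  fx <- block_design_fixture()
  n_vox <- 10000
  set.seed(123)
  Y <- matrix(100 + rnorm(248 * n_vox), 248, n_vox)
  fit <- fit_block_glm(Y, fx$X)
  t <- t_contrast(fit, contrast_vs_rest(fit, "scenery"))$t
  rate <- mean(t >= 1.96)
  expect_gt(rate, 0.020)
  expect_lt(rate, 0.030)
})

test_that("AR(1) noise inflates the null rate; the correction tempers it", {
  fx <- block_design_fixture()
  n_vox <- 4000
  vox <- tibble::tibble(subject = 1, roi = "V1", voxel = seq_len(n_vox),
                        kind = "null", mu = NA, sigma = NA, amplitude = 0,
                        scenery_gain = NA, noise_sd = 1, ar1 = 0.3, drift = 0)
  run <- simulate_bold_run(vox, fx$tl, seed = 9)
  plain <- fit_block_glm(run$signal, fx$X)
  corrected <- fit_block_glm(run$signal, fx$X, ar_correction = TRUE)
  rate_plain <- mean(t_contrast(plain, contrast_vs_rest(plain, "scenery"))$t
                     >= 1.96)
  rate_corr <- mean(t_contrast(corrected,
                               contrast_vs_rest(corrected, "scenery"))$t
                    >= 1.96)
  expect_gt(rate_plain, 0.025)   # inflation documented, not hidden
  expect_lt(rate_corr, rate_plain)
})

test_that("scenery-responsive voxels clear the exclusion threshold", {
  # full default session: seven concatenated block runs
  vox <- tibble::tibble(subject = 1, roi = "PPA", voxel = 1:100,
                        kind = "scenery_responsive", mu = NA, sigma = NA,
                        amplitude = 1.5, scenery_gain = NA, noise_sd = 1,
                        ar1 = 0.3, drift = 0.2)
  tls <- lapply(1:7, function(i) build_block_timeline(shared_manifest(),
                                                      seed = 60 + i))
  runs <- lapply(seq_along(tls), function(i)
    simulate_bold_run(vox, tls[[i]], seed = 80 + i))
  X <- build_design_matrix(tls, n_timepoints = rep(248, 7))
  fit <- fit_block_glm(runs, X)
  t <- t_contrast(fit, contrast_vs_rest(fit, "scenery"))$t
  expect_gt(mean(t >= 1.96), 0.95)
})
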