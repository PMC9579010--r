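test_that("signed-rank exact p values match printed small-sample cases", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7))$p_value, 1 / 128)
  expect_equal(wilcoxon_signed_rank(2.5)$p_value, 0.5)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  # zeros are dropped before ranking
  r <- wilcoxon_signed_rank(c(0, 1, 2, 3))
  expect_equal(r$n, 3)
  expect_equal(r$zeros_dropped, 1)
  expect_equal(r$p_value, 1 / 8)
})

test_that("exact null distribution equals full 2^n enumeration (n <= 10)", {
  set.seed(99)
  for (n in 3:10) {
    # distinct magnitudes and tied magnitudes both enumerate exactly
    for (d in list(rnorm(n), round(rnorm(n), 0) + 0.5 * sign(rnorm(n)))) {
      d <- d[d != 0]
      if (length(d) < 2) next
      expect_equal(wilcoxon_signed_rank(d)$p_value,
                   enumerate_signed_rank_p(d),
                   info = sprintf("n = %d", n))
    }
  }
})

test_that("untied exact p agrees with the reference distribution function", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    x <- rnorm(n) + 0.4
    x <- x[x != 0]
    ours <- wilcoxon_signed_rank(x)
    ref <- 1 - stats::psignrank(ours$statistic - 1, length(x))
    expect_equal(ours$p_value, ref)
    # and with the standard implementation on the same data
    wt <- suppressWarnings(stats::wilcox.test(x, alternative = "greater",
                                              exact = TRUE))
    expect_equal(ours$p_value, unname(wt$p.value))
  }
})

test_that("large samples use the corrected normal approximation", {
  set.seed(8)
  x <- rnorm(40) + 0.3
  ours <- wilcoxon_signed_rank(x)
  expect_equal(ours$method, "normal_approx")
  wt <- suppressWarnings(stats::wilcox.test(x, alternative = "greater",
                                            exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, unname(wt$p.value), tolerance = 1e-10)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$p_adjusted,
               rep(0.04, 4))
  expect_equal(bh_adjust(0.2)$p_adjusted, 0.2)
  set.seed(5)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)$p_adjusted
    expect_equal(adj, brute_force_bh(p))
    expect_equal(adj, stats::p.adjust(p, "BH"))
  }
  # order equivariance
  p <- runif(8)
  perm <- sample(8)
  expect_equal(bh_adjust(p[perm])$p_adjusted, bh_adjust(p)$p_adjusted[perm])
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_equal(nrow(bh_adjust(numeric())), 0)
})

test_that("roi table averages the right voxel sets", {
  psc_long <- tidyr::expand_grid(subject = 1, roi = c("NPC1", "V1"),
                                 voxel = 1:4, category = c("nat_low", "scenery"))
  psc_long$psc <- seq_len(nrow(psc_long))
  psc_long$selected <- psc_long$voxel <= 2
  psc_long$mask_pass <- psc_long$voxel %in% c(2, 3, 4)
  tb <- roi_response_table(psc_long, apply_scenery_mask = TRUE)
  # numerosity map: selected & mask -> only voxel 2
  npc <- dplyr::filter(tb, roi == "NPC1", category == "nat_low")
  expect_equal(npc$n_voxels, 1)
  v2 <- dplyr::filter(psc_long, roi == "NPC1", category == "nat_low",
                      voxel == 2)
  expect_equal(npc$mean_psc, v2$psc)
  # control ROI: all voxels regardless of mask
  v1 <- dplyr::filter(tb, roi == "V1", category == "nat_low")
  expect_equal(v1$n_voxels, 4)
  # disabling the mask leaves control rows unchanged
  tb2 <- roi_response_table(psc_long, apply_scenery_mask = FALSE)
  expect_equal(dplyr::filter(tb2, roi == "V1"), dplyr::filter(tb, roi == "V1"),
               ignore_attr = TRUE)
  expect_equal(dplyr::filter(tb2, roi == "NPC1", category == "nat_low")$n_voxels,
               2)
  # empty voxel set gives count 0 and a missing mean
  psc_long$selected <- FALSE
  tb3 <- roi_response_table(psc_long)
  expect_true(all(is.na(dplyr::filter(tb3, roi == "NPC1")$mean_psc)))
  expect_true(all(dplyr::filter(tb3, roi == "NPC1")$n_voxels == 0))
})

test_that("positivity tests separate responsive from silent categories", {
  set.seed(31)
  cells <- tidyr::expand_grid(subject = 1:7, roi = c("PPA", "V1"),
                              category = block_categories())
  cells$mean_psc <- ifelse(
    cells$roi == "V1", 1 + rnorm(nrow(cells), 0, 0.1),
    ifelse(cells$category %in% c("nat_low", "nat_high", "scenery"),
           1.5 + rnorm(nrow(cells), 0, 0.1), rnorm(nrow(cells), 0, 0.1)))
  cells$n_voxels <- 10
  res <- test_positive_response(cells)
  ppa <- dplyr::filter(res, roi == "PPA")
  expect_true(all(ppa$significant[ppa$category %in%
                                    c("nat_low", "nat_high", "scenery")]))
  expect_false(any(ppa$significant[startsWith(ppa$category, "dot")]))
  expect_true(all(dplyr::filter(res, roi == "V1")$significant))
  expect_false(any(res$low_power))
  # all-negative responses give p well above one half
  neg <- dplyr::mutate(cells, mean_psc = -abs(mean_psc) - 0.1)
  res_neg <- test_positive_response(neg)
  expect_true(all(res_neg$p_value > 0.5))
  # n < 4 cells are flagged but still tested
  small <- dplyr::filter(cells, subject <= 3)
  res_small <- test_positive_response(small)
  expect_true(all(res_small$low_power))
  expect_true(all(!is.na(res_small$p_value)))
})

test_that("identical positive cohorts share one adjusted p", {
  cells <- tidyr::expand_grid(subject = 1:7, roi = "NPC1",
                              category = block_categories())
  cells$mean_psc <- rep(c(1, 1.1, 0.9, 1.2, 1.05, 0.95, 1.15), each = 6)
  cells$n_voxels <- 10
  res <- test_positive_response(cells)
  expect_equal(length(unique(res$p_adjusted)), 1)
})

test_that("low-vs-high testing handles direction, absence and degeneracy", {
  make_table <- function(low, high) {
    tb <- tidyr::expand_grid(subject = 1:7,
                             roi = setdiff(numerosity_maps(), "NF"),
                             category = c("nat_low", "nat_high",
                                          "dot_low", "dot_high"))
    tb$mean_psc <- ifelse(tb$category %in% c("nat_low", "dot_low"),
                          low[tb$subject], high[tb$subject])
    tb$n_voxels <- 10
    tb
  }
  set.seed(44)
  lo <- 1.5 + rnorm(7, 0, 0.05)
  hi <- 0.3 + rnorm(7, 0, 0.05)
  res <- test_low_vs_high(make_table(lo, hi))
  nat <- dplyr::filter(res, comparison == "natural low > high")
  expect_equal(nrow(nat), 5)
  expect_true(all(nat$significant))
  expect_equal(unique(nat$p_value), 1 / 128)
  # reversed tuning gives the opposite direction
  rev <- test_low_vs_high(make_table(hi, lo))
  expect_true(all(dplyr::filter(rev, comparison ==
                                  "natural low > high")$p_value > 0.9))
  # a missing category is a named error
  tb <- make_table(lo, hi)
  expect_error(test_low_vs_high(dplyr::filter(tb, category != "nat_high")),
               "nat_high")
  # all-zero differences are untestable, not silently dropped
  tied <- make_table(lo, lo)
  res_tied <- test_low_vs_high(tied, include_dots = FALSE)
  expect_true(all(res_tied$untestable))
  expect_true(all(is.na(res_tied$p_value)))
})
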