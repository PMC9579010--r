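#' One-sided Wilcoxon signed-rank test
#'
#' Tests whether paired differences (or a single sample against `mu0`) are
#' stochastically greater than zero. Zero differences are dropped before
#' ranking (their count is reported); ties share midranks. For up to
#' `exact_max_n` non-zero values the null distribution of the positive-rank
#' sum is computed exactly over all sign assignments of the observed ranks
#' (by dynamic programming, identical to full 2^n enumeration); above that a
#' normal approximation with continuity and tie correction is used.
#'
#' @param x Numeric values (differences, or the first sample).
#' @param y Optional second sample for a paired test (`x - y` is tested).
#' @param mu0 Null location when `y` is absent.
#' @param exact_max_n Largest n for the exact null distribution.
#' @return A one-row tibble: `n` (non-zero values used), `statistic` (sum of
#'   positive ranks), `p_value` (one-sided, greater), `method`,
#'   `zeros_dropped`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7))$p_value  # 1/128
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu0 = 0, exact_max_n = 25) {
  d <- if (is.null(y)) x - mu0 else x - y
  d <- d[!is.na(d)]
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("All differences are zero (or missing): signed-rank test undefined.")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])

  if (n <= exact_max_n) {
    # Exact tail over the 2^n sign assignments, via subset-sum DP on doubled
    # midranks (doubling keeps half-integer midranks integral).
    d2 <- as.integer(round(2 * rk))
    total <- sum(d2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (r in d2) {
      shifted <- c(numeric(r), f[seq_len(total + 1 - r)])
      f <- f + shifted
    }
    w2 <- as.integer(round(2 * W))
    p <- sum(f[(w2 + 1):(total + 1)]) / 2^n
    method <- "exact"
  } else {
    mean_w <- n * (n + 1) / 4
    ties <- table(rk)
    var_w <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mean_w - 0.5) / sqrt(var_w)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal_approx"
  }
  tibble(n = n, statistic = W, p_value = p, method = method,
         zeros_dropped = zeros)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values: `p_adj(i) = min_{j >= i} m * p(j) / j` over
#' the sorted values, capped at 1 and mapped back to the input order.
#' Rejection means `p_adj < alpha`.
#'
#' @param p Numeric p values in (0, 1].
#' @param alpha FDR level.
#' @return A tibble with `p`, `p_adjusted`, `significant`, in input order
#'   (empty input gives an empty tibble).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (!length(p)) {
    return(tibble(p = numeric(), p_adjusted = numeric(),
                  significant = logical()))
  }
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    abort("All p values must lie in (0, 1].")
  }
  m <- length(p)
  o <- order(p)
  ranked <- m * p[o] / seq_len(m)
  adj_sorted <- pmin(rev(cummin(rev(ranked))), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  tibble(p = p, p_adjusted = adj, significant = adj < alpha)
}

#' Subject x ROI x category response table
#'
#' Averages per-voxel percent-signal responses into one row per (subject,
#' ROI, category). Numerosity-map rows average only voxels in the tuned
#' selection, intersected with the scenery inclusion mask when
#' `apply_scenery_mask` is on; control ROIs (V1, LO, PPA) average all their
#' voxels. Empty voxel sets yield a row with `n_voxels = 0` and a missing
#' mean.
#'
#' @param psc_long Voxel-level tibble with columns `subject`, `roi`,
#'   `voxel`, `category`, `psc`, `selected` (tuned-selection membership)
#'   and `mask_pass` (scenery mask).
#' @param apply_scenery_mask Intersect numerosity-map selections with the
#'   scenery mask?
#' @param maps Which ROIs are numerosity maps.
#' @return A tibble of class `nt_roi_table`: `subject`, `roi`, `category`,
#'   `mean_psc`, `n_voxels`.
#' @export
roi_response_table <- function(psc_long, apply_scenery_mask = TRUE,
                               maps = numerosity_maps()) {
  needed <- c("subject", "roi", "voxel", "category", "psc", "selected",
              "mask_pass")
  missing <- setdiff(needed, names(psc_long))
  if (length(missing)) {
    abort(sprintf("`psc_long` lacks columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- psc_long |>
    dplyr::mutate(use = ifelse(.data$roi %in% maps,
                               .data$selected &
                                 (!apply_scenery_mask | .data$mask_pass),
                               TRUE)) |>
    dplyr::group_by(.data$subject, .data$roi, .data$category) |>
    dplyr::summarise(
      mean_psc = if (any(.data$use)) mean(.data$psc[.data$use]) else NA_real_,
      n_voxels = sum(.data$use), .groups = "drop")
  structure(out, class = c("nt_roi_table", class(tibble())),
            scenery_mask = apply_scenery_mask)
}

#' Positive-response tests per ROI and category
#'
#' One one-sided Wilcoxon signed-rank test (response > 0) per ROI x
#' category cell, across subjects, followed by Benjamini-Hochberg
#' adjustment over all cells tested in the call (the per-figure family).
#' Cells with fewer than four subjects are flagged low-power but still
#' tested.
#'
#' @param roi_table An [roi_response_table()] result (or compatible tibble).
#' @param rois Restrict to these ROIs (default: all present).
#' @param alpha FDR level.
#' @return A tibble of class `nt_test_result`: `roi`, `comparison`, `n`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`, `low_power`.
#' @export
test_positive_response <- function(roi_table, rois = NULL, alpha = 0.05) {
  tb <- as_tibble(roi_table)
  if (!is.null(rois)) tb <- dplyr::filter(tb, .data$roi %in% rois)
  tb <- dplyr::filter(tb, !is.na(.data$mean_psc))
  if (nrow(tb) == 0) {
    warn("No testable ROI x category cells (all means missing).")
    out <- tibble(roi = character(), category = character(),
                  comparison = character(), n = integer(),
                  statistic = numeric(), p_value = numeric(),
                  p_adjusted = numeric(), significant = logical(),
                  low_power = logical())
    return(structure(out, class = c("nt_test_result", class(tibble())),
                     alpha = alpha))
  }
  res <- tb |>
    dplyr::group_by(.data$roi, .data$category) |>
    dplyr::summarise(test = list(wilcoxon_signed_rank(.data$mean_psc)),
                     .groups = "drop") |>
    tidyr::unnest("test") |>
    dplyr::mutate(comparison = paste0(.data$category, " > 0"),
                  low_power = .data$n < 4)
  adj <- bh_adjust(res$p_value, alpha)
  out <- dplyr::select(
    dplyr::mutate(res, p_adjusted = adj$p_adjusted,
                  significant = adj$significant),
    "roi", "category", "comparison", "n", "statistic", "p_value",
    "p_adjusted", "significant", "low_power")
  structure(out, class = c("nt_test_result", class(tibble())), alpha = alpha)
}

#' Low- versus high-numerosity response tests per map
#'
#' For each numerosity map, a paired one-sided Wilcoxon signed-rank test of
#' the subject-level difference between the low-numerosity (1-3 objects)
#' and high-numerosity (10-42 objects) natural-image responses, with
#' Benjamini-Hochberg adjustment across maps. The frontal maps are excluded
#' by default (too few subjects carry them). The analogous dot-category
#' comparison is computed alongside as its own family.
#'
#' @param roi_table An [roi_response_table()] result.
#' @param maps Numerosity maps to test (frontal maps excluded by default).
#' @param alpha FDR level.
#' @param include_dots Also test the dot-category analogue?
#' @return An `nt_test_result` tibble; untestable maps (all-zero
#'   differences) carry `p_value = NA` and `untestable = TRUE`.
#' @export
test_low_vs_high <- function(roi_table, maps = setdiff(numerosity_maps(), "NF"),
                             alpha = 0.05, include_dots = TRUE) {
  tb <- as_tibble(roi_table)
  one_family <- function(low, high, label) {
    for (cat in c(low, high)) {
      if (!cat %in% tb$category) {
        abort(sprintf("Response table lacks the '%s' category.", cat))
      }
    }
    wide <- tb |>
      dplyr::filter(.data$roi %in% maps,
                    .data$category %in% c(low, high)) |>
      dplyr::select("subject", "roi", "category", "mean_psc") |>
      tidyr::pivot_wider(names_from = "category", values_from = "mean_psc")
    if (!all(c(low, high) %in% names(wide))) {
      wide[setdiff(c(low, high), names(wide))] <- NA_real_
    }
    wide <- dplyr::filter(wide, !is.na(.data[[low]]), !is.na(.data[[high]]))
    if (nrow(wide) == 0) {
      warn(sprintf("No testable subjects for '%s' (all means missing).",
                   label))
      return(tibble(roi = character(), comparison = character(),
                    n = integer(), statistic = numeric(),
                    p_value = numeric(), p_adjusted = numeric(),
                    significant = logical(), low_power = logical(),
                    untestable = logical()))
    }
    res <- wide |>
      dplyr::group_by(.data$roi) |>
      dplyr::summarise(test = list(tryCatch(
        wilcoxon_signed_rank(.data[[low]], .data[[high]]),
        error = function(e) tibble(n = dplyr::n(), statistic = NA_real_,
                                   p_value = NA_real_, method = "untestable",
                                   zeros_dropped = NA_integer_))),
        .groups = "drop") |>
      tidyr::unnest("test") |>
      dplyr::mutate(comparison = label,
                    untestable = .data$method == "untestable",
                    low_power = .data$n < 4)
    testable <- !is.na(res$p_value)
    res$p_adjusted <- NA_real_
    res$significant <- NA
    if (any(testable)) {
      adj <- bh_adjust(res$p_value[testable], alpha)
      res$p_adjusted[testable] <- adj$p_adjusted
      res$significant[testable] <- adj$significant
    }
    dplyr::select(res, "roi", "comparison", "n", "statistic", "p_value",
                  "p_adjusted", "significant", "low_power", "untestable")
  }
  out <- one_family("nat_low", "nat_high", "natural low > high")
  if (include_dots) {
    out <- dplyr::bind_rows(out, one_family("dot_low", "dot_high",
                                            "dots low > high"))
  }
  structure(out, class = c("nt_test_result", class(tibble())), alpha = alpha)
}
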