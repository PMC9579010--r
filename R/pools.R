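#' Stimulus pool specification
#'
#' Sizes and image geometry for the per-category stimulus pools. The
#' natural-image pools default to 93 one-object, 95 two-object and 70
#' three-object images (together the "low numerosity" category), 70
#' high-numerosity images (10-42 objects) and 61 scenery images; the three
#' dot-display pools default to 64 entries each.
#'
#' @param n_one,n_two,n_three,n_high,n_scenery Natural-image pool sizes.
#' @param n_dot_low,n_dot_20,n_dot_high Dot-display pool sizes.
#' @param image_px Side length of generated fixture images, pixels.
#' @param high_range Inclusive object-count range of the high-numerosity
#'   category.
#' @param high_mean,high_sd Target moments of the high-numerosity count
#'   distribution.
#' @return A list of class `pool_spec`.
#' @export
pool_spec <- function(n_one = 93, n_two = 95, n_three = 70, n_high = 70,
                      n_scenery = 61, n_dot_low = 64, n_dot_20 = 64,
                      n_dot_high = 64, image_px = 128,
                      high_range = c(10L, 42L),
                      high_mean = 19.42, high_sd = 8.8) {
  sizes <- c(n_one, n_two, n_three, n_high, n_scenery,
             n_dot_low, n_dot_20, n_dot_high)
  if (any(sizes < 0) || any(sizes != round(sizes))) {
    abort("Pool sizes must be non-negative integers.")
  }
  if (image_px < 64) abort("`image_px` must be at least 64.")
  structure(list(n_one = n_one, n_two = n_two, n_three = n_three,
                 n_high = n_high, n_scenery = n_scenery,
                 n_dot_low = n_dot_low, n_dot_20 = n_dot_20,
                 n_dot_high = n_dot_high, image_px = image_px,
                 high_range = as.integer(high_range),
                 high_mean = high_mean, high_sd = high_sd),
            class = "pool_spec")
}

# Cache for calibrated high-numerosity samplers, keyed by target settings.
.sampler_cache <- new.env(parent = emptyenv())

# Probability mass function of a discretized Beta distribution scaled to
# `range` (integer k gets the Beta mass of [k - 0.5, k + 0.5]), with the two
# shape parameters solved numerically by moment matching to (mean, sd). A
# scaled Beta is used because the target moments sit near the edge of what
# right-skewed unimodal families can reach on this narrow support.
high_count_pmf <- function(range = c(10L, 42L), mean = 19.42, sd = 8.8) {
  key <- paste(range[1], range[2], mean, sd, sep = "_")
  hit <- get0(key, .sampler_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  k <- seq.int(range[1], range[2])
  lo <- range[1] - 0.5
  width <- diff(range) + 1
  pmf_of <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    p <- stats::pbeta((k + 0.5 - lo) / width, a, b) -
      stats::pbeta((k - 0.5 - lo) / width, a, b)
    p / sum(p)
  }
  objective <- function(par) {
    p <- pmf_of(par)
    m <- sum(k * p)
    s <- sqrt(sum((k - m)^2 * p))
    (m - mean)^2 + (s - sd)^2
  }
  fit <- optim(c(log(0.5), log(1.2)), objective, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
  if (fit$value > 1e-6) {
    warn(sprintf("High-count sampler calibration residual %.2g: target moments may be unreachable on [%d, %d].",
                 fit$value, range[1], range[2]))
  }
  out <- list(k = k, pmf = pmf_of(fit$par), par = fit$par, value = fit$value)
  assign(key, out, .sampler_cache)
  out
}

#' Sample high-numerosity object counts
#'
#' Draws integer object counts for the high-numerosity natural-image
#' category from a discretized Beta distribution scaled to `high_range`,
#' calibrated by two-moment matching so the long-run mean and SD equal the
#' category's empirical moments (19.42 and 8.8 by default).
#'
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param spec A [pool_spec()] carrying the range and target moments.
#' @return Integer vector of counts, all within `high_range`.
#' @examples
#' x <- sample_high_numerosity(1000, seed = 1)
#' range(x)  # within 10..42
#' @export
sample_high_numerosity <- function(n = 1, seed = NULL, spec = pool_spec()) {
  pm <- high_count_pmf(spec$high_range, spec$high_mean, spec$high_sd)
  draw <- function() sample(pm$k, n, replace = TRUE, prob = pm$pmf)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Build a stimulus pool manifest
#'
#' Enumerates every pool entry (synthetic natural-image fixtures and dot
#' displays) with its exact object-count annotation. No files are written;
#' [generate_fixture_pool()] renders the images listed here.
#'
#' @param spec A [pool_spec()].
#' @param seed Integer seed controlling the high-numerosity annotations and
#'   the dot-pool numerosities.
#' @return A tibble of class `pool_manifest` with columns `category`,
#'   `item_kind` (`"image"` or `"dots"`), `item_id`, `n_objects`
#'   (`NA` for scenery) and `path` (`NA` until images are written).
#' @export
build_pool_manifest <- function(spec = pool_spec(), seed = 1) {
  seeds <- derive_seeds(seed, 2, salt = 11L)
  entry <- function(category, kind, n, counts) {
    if (n == 0L) {
      return(tibble(category = character(), item_kind = character(),
                    item_id = character(), n_objects = integer(),
                    path = character()))
    }
    tibble(category = category, item_kind = kind,
           item_id = sprintf("%s_%03d", category, seq_len(n)),
           n_objects = as.integer(counts), path = NA_character_)
  }
  high_counts <- sample_high_numerosity(spec$n_high, seed = seeds[1], spec = spec)
  dot_low_n <- with_seed(seeds[2], sample(1:3, spec$n_dot_low, replace = TRUE))
  dot_high_n <- sample_high_numerosity(spec$n_dot_high, seed = seeds[2] + 1L, spec = spec)
  out <- dplyr::bind_rows(
    entry("nat_one", "image", spec$n_one, 1L),
    entry("nat_two", "image", spec$n_two, 2L),
    entry("nat_three", "image", spec$n_three, 3L),
    entry("nat_high", "image", spec$n_high, high_counts),
    entry("scenery", "image", spec$n_scenery, NA_integer_),
    entry("dot_low", "dots", spec$n_dot_low, dot_low_n),
    entry("dot_20", "dots", spec$n_dot_20, 20L),
    entry("dot_high", "dots", spec$n_dot_high, dot_high_n)
  )
  structure(out, class = c("pool_manifest", class(out)),
            spec = spec, seed = seed)
}

#' Synthesize one natural-image fixture
#'
#' Builds a grayscale image with the 1/f amplitude spectrum characteristic
#' of natural scenes: a random-phase power-law background, plus `n_objects`
#' Gaussian-profile bright blobs standing in for discrete objects (scenery
#' fixtures are blob-free texture). Blob contrast is kept modest so the
#' inserted objects perturb the radial amplitude spectrum by less than the
#' slope-fit tolerance.
#'
#' @param n_objects Integer object count, or `NA` for scenery.
#' @param size Image side, pixels (>= 64).
#' @param seed Integer seed.
#' @param beta Spectral exponent of the background (amplitude ~ f^beta).
#' @param blob_contrast Peak amplitude of each object blob, image units.
#' @return A `size` x `size` numeric matrix with values in [0, 1].
#' @export
fixture_image <- function(n_objects, size = 128, seed = 1, beta = -1,
                          blob_contrast = 0.25) {
  if (size < 64) abort("Fixture images must be at least 64 px a side.")
  with_seed(seed, {
    img <- power_law_field(size, beta)
    img <- 0.5 + 0.12 * img / sd(img)
    if (!is.na(n_objects) && n_objects > 0) {
      xs <- seq_len(size)
      for (i in seq_len(n_objects)) {
        cx <- runif(1, 0.1 * size, 0.9 * size)
        cy <- runif(1, 0.1 * size, 0.9 * size)
        bsd <- runif(1, 0.02 * size, 0.045 * size)
        blob <- blob_contrast *
          exp(-(outer((xs - cx)^2, rep(1, size)) +
                  outer(rep(1, size), (xs - cy)^2)) / (2 * bsd^2))
        img <- img + blob
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Generate the on-disk fixture pool
#'
#' Renders every image entry of a [build_pool_manifest()] to PNG and writes
#' the manifest (TSV plus JSON with the generating seed) beside them.
#'
#' @param spec A [pool_spec()].
#' @param seed Integer seed; the whole pool is reproducible from it.
#' @param out_dir Output directory.
#' @param overwrite Overwrite an existing manifest? Default `FALSE` (error
#'   on collision).
#' @param write_images Set `FALSE` to write only the manifest.
#' @return The manifest tibble with `path` filled in for image entries.
#' @export
generate_fixture_pool <- function(spec = pool_spec(), seed = 1, out_dir,
                                  overwrite = FALSE, write_images = TRUE) {
  manifest_path <- file.path(out_dir, "pool_manifest.tsv")
  if (file.exists(manifest_path) && !overwrite) {
    abort(sprintf("Manifest already exists at '%s' (set overwrite = TRUE).",
                  manifest_path))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- build_pool_manifest(spec, seed)
  img_rows <- which(manifest$item_kind == "image")
  img_seeds <- derive_seeds(seed, max(length(img_rows), 1L), salt = 23L)
  if (write_images && length(img_rows)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("Writing fixture images requires the 'png' package.")
    }
    for (j in seq_along(img_rows)) {
      i <- img_rows[j]
      img <- fixture_image(manifest$n_objects[i], size = spec$image_px,
                           seed = img_seeds[j])
      p <- file.path(out_dir, paste0(manifest$item_id[i], ".png"))
      png::writePNG(img, p)
      manifest$path[i] <- p
    }
  }
  readr::write_tsv(as_tibble(manifest), manifest_path)
  jsonlite::write_json(list(seed = seed, image_px = spec$image_px,
                            n_entries = nrow(manifest)),
                       file.path(out_dir, "pool_manifest.json"),
                       auto_unbox = TRUE)
  manifest
}
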