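#' Generate a random dot-array display
#'
#' Places `n` non-overlapping dots uniformly at random inside a circular
#' stimulus field, under one of the two magnitude-control regimes used in
#' numerosity experiments: `constant_total_area` keeps the summed dot surface
#' area fixed across numerosities (so contrast energy does not covary with
#' number), while `constant_dot_size` keeps the individual dot radius fixed.
#'
#' Placement is by rejection sampling: candidate centers are drawn uniformly
#' over the field (shrunk by the dot radius so dots lie fully inside) and
#' rejected on overlap. Dots must clear each other by a 10% of a radius
#' margin beyond tangency so rendered dots stay visually separable.
#'
#' @param n Positive integer numerosity (dot count).
#' @param mode `"constant_total_area"` or `"constant_dot_size"`.
#' @param field_diameter Stimulus field diameter, degrees of visual angle.
#' @param seed Integer seed; identical `(n, mode, seed)` give identical
#'   geometry.
#' @param total_area Total dot surface area (deg^2) in
#'   `constant_total_area` mode. Default: the area of a single dot of 0.4
#'   degrees diameter.
#' @param dot_radius Per-dot radius (deg) in `constant_dot_size` mode.
#' @param polarity `"black"` or `"white"` (white dots are the attention
#'   oddballs).
#' @param max_tries Rejection-sampling retry budget per display.
#' @return A list of class `dot_display` with fields `centers` (n x 2 matrix,
#'   deg), `radii`, `numerosity`, `field_diameter`, `mode`, `polarity`.
#' @examples
#' d <- generate_dot_display(20, "constant_total_area", seed = 1)
#' sum(pi * d$radii^2)  # == configured total area
#' @export
generate_dot_display <- function(n, mode = c("constant_total_area", "constant_dot_size"),
                                 field_diameter = 4, seed = 1,
                                 total_area = pi * 0.2^2, dot_radius = 0.1,
                                 polarity = c("black", "white"),
                                 max_tries = 10000) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer numerosity.")
  }
  n <- as.integer(n)
  assert_scalar_number(field_diameter, "field_diameter", lower = 1e-6)

  r <- if (mode == "constant_total_area") sqrt(total_area / (n * pi)) else dot_radius
  R <- field_diameter / 2
  if (r >= R) abort("Dot radius exceeds the field radius; placement infeasible.")
  min_dist <- 2.1 * r  # tangency plus a 0.1-radius separability gap

  centers <- with_seed(seed, {
    out <- matrix(NA_real_, n, 2)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf(
          "Could not place %d non-overlapping dots of radius %.4g in a %.3g deg field after %d tries.",
          n, r, field_diameter, max_tries))
      }
      rad <- (R - r) * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      cand <- c(rad * cos(th), rad * sin(th))
      if (placed > 0L) {
        d2 <- (out[seq_len(placed), 1] - cand[1])^2 + (out[seq_len(placed), 2] - cand[2])^2
        if (any(d2 < min_dist^2)) next
      }
      placed <- placed + 1L
      out[placed, ] <- cand
    }
    out
  })

  structure(list(centers = centers, radii = rep(r, n), numerosity = n,
                 field_diameter = field_diameter, mode = mode,
                 polarity = polarity,
                 total_area = if (mode == "constant_total_area") total_area else n * pi * r^2),
            class = "dot_display")
}

#' Rasterize a dot display to a binary image
#'
#' Renders the display onto a square pixel grid covering the bounding square
#' of the circular field. A pixel is on iff its center lies inside a dot.
#'
#' @param display A [generate_dot_display()] result.
#' @param side_px Image side in pixels. The default resolves the smallest dot
#'   with at least 5 pixels of radius (and at least 256 pixels a side) so
#'   that distinct dots never touch in the raster.
#' @return A logical `side_px` x `side_px` matrix.
#' @export
render_dot_display <- function(display, side_px = NULL) {
  stopifnot(inherits(display, "dot_display"))
  r <- min(display$radii)
  D <- display$field_diameter
  if (is.null(side_px)) side_px <- max(256L, ceiling(20 * D / r))
  px <- seq(-D / 2, D / 2, length.out = side_px)
  img <- matrix(FALSE, side_px, side_px)
  for (i in seq_len(display$numerosity)) {
    cx <- display$centers[i, 1]; cy <- display$centers[i, 2]; ri <- display$radii[i]
    xi <- which(abs(px - cx) <= ri)
    yi <- which(abs(px - cy) <= ri)
    if (!length(xi) || !length(yi)) next
    sub <- outer(px[xi] - cx, rep(1, length(yi)))^2 +
      outer(rep(1, length(xi)), px[yi] - cy)^2
    img[xi, yi] <- img[xi, yi] | (sub <= ri^2)
  }
  img
}

# 4-connected component count, used as an independent check that a raster
# contains exactly `numerosity` separate dots.
count_components <- function(img) {
  lab <- matrix(0L, nrow(img), ncol(img))
  nxt <- 0L
  idx <- which(img)
  nr <- nrow(img)
  for (p in idx) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    stack <- p
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[q] != 0L) next
      lab[q] <- nxt
      i <- ((q - 1L) %% nr) + 1L
      j <- ((q - 1L) %/% nr) + 1L
      nb <- integer(0)
      if (i > 1L) nb <- c(nb, q - 1L)
      if (i < nr) nb <- c(nb, q + 1L)
      if (j > 1L) nb <- c(nb, q - nr)
      if (j < ncol(img)) nb <- c(nb, q + nr)
      nb <- nb[img[nb] & lab[nb] == 0L]
      stack <- c(stack, nb)
    }
  }
  nxt
}
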