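# Maximum region of interest. Cell interiors share the background gray
# level but are full of minor structures, so local gradient — not intensity —
# separates cells from background. Canny maps at three scales are merged by
# OR and flowed through binary morphology into a permissive mask meant to
# cover every cell event (background inclusions are harmless downstream).

#' Averaged 2x2 finite-difference gradient field
#'
#' Computes the gradient with the averaged forward-difference stencil
#' `gx = (f(x+1,y) - f(x,y) + f(x+1,y+1) - f(x,y+1)) / 2` (and symmetrically
#' `gy`), where `x` indexes columns and `y` rows. The field is defined on the
#' `(height-1) x (width-1)` valid grid of the 2x2 stencil. Edge strength is
#' `sqrt(gx^2 + gy^2)` and edge direction `atan2(gy, gx)`.
#'
#' @param image Numeric matrix in \[0,1\] (at least 2x2).
#' @return An object of class `hma_gradient`: list with `gx`, `gy`,
#'   `magnitude`, `direction`, each `(nrow-1) x (ncol-1)`.
#' @examples
#' g <- finite_difference_gradient(matrix(rep(0:3 / 10, 4), 4, 4, byrow = TRUE))
#' g$gx[1, 1]  # 0.1 per column step
#' @export
finite_difference_gradient <- function(image) {
  image <- as_numeric_matrix(image)
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 2 || nc < 2)
    stop("image must be at least 2x2 for the 2x2 gradient stencil", call. = FALSE)
  a <- image[-nr, -nc, drop = FALSE]  # f(x,   y)
  b <- image[-nr, -1,  drop = FALSE]  # f(x+1, y)
  d <- image[-1,  -nc, drop = FALSE]  # f(x,   y+1)
  e <- image[-1,  -1,  drop = FALSE]  # f(x+1, y+1)
  gx <- (b - a + e - d) / 2
  gy <- (d - a + e - b) / 2
  structure(list(gx = gx, gy = gy,
                 magnitude = sqrt(gx^2 + gy^2),
                 direction = atan2(gy, gx)),
            class = "hma_gradient")
}

# Sobel gradient with replicated borders (used inside canny_edges)
sobel_gradient <- function(image) {
  sx <- shift_replicate(image, 0, -1) - shift_replicate(image, 0, 1)
  sy <- shift_replicate(image, -1, 0) - shift_replicate(image, 1, 0)
  gx <- 2 * sx +
    (shift_replicate(image, -1, -1) - shift_replicate(image, -1, 1)) +
    (shift_replicate(image,  1, -1) - shift_replicate(image,  1, 1))
  gy <- 2 * sy +
    (shift_replicate(image, -1, -1) - shift_replicate(image, 1, -1)) +
    (shift_replicate(image, -1,  1) - shift_replicate(image, 1,  1))
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

#' Canny edge detection
#'
#' Standard Canny flow: Gaussian smoothing, Sobel gradient, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' linking (weak-edge components are kept only if they contain a strong
#' pixel). Thresholds are fractions of the maximum gradient magnitude; by
#' default the high threshold is the Otsu split of the nonzero magnitudes
#' and the low threshold is 0.4 times the high one.
#'
#' @param image Numeric matrix in \[0,1\].
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `0 < low < high < 1`, or `NULL` for automatic
#'   selection.
#' @return Logical matrix of edge pixels, same shape as `image`.
#' @export
canny_edges <- function(image, sigma = 1.0, low = NULL, high = NULL) {
  image <- check_intensity_image(image)
  if (!is.null(low) && !is.null(high) && !(low > 0 && low < high && high < 1))
    stop("thresholds must satisfy 0 < low < high < 1", call. = FALSE)
  sm <- iterated_gaussian(image, sigma = sigma, n = 1L,
                          radius = max(3L, ceiling(3 * sigma)))
  g <- sobel_gradient(sm)
  m <- g$magnitude
  mmax <- max(m)
  # gradients at rounding-noise level mean a flat image, not edges
  if (mmax < 1e-8) return(matrix(FALSE, nrow(image), ncol(image)))
  mn <- m / mmax

  # non-maximum suppression in 4 quantized directions
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  nb <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(m), ncol(m))
  for (s in 0:3) {
    d <- nb[[s + 1L]]
    fwd <- shift_replicate(m,  d[1],  d[2])
    bwd <- shift_replicate(m, -d[1], -d[2])
    sel <- sector == s & m >= fwd & m >= bwd
    keep[sel] <- TRUE
  }
  mn[!keep] <- 0

  if (is.null(high)) {
    nz <- mn[mn > 0]
    if (length(unique(nz)) < 2) return(matrix(FALSE, nrow(image), ncol(image)))
    high <- multilevel_otsu(nz / max(nz), k = 1L) * max(nz)
  }
  if (is.null(low)) low <- 0.4 * high

  strong <- mn >= high
  weak <- mn >= low
  if (!any(strong)) return(matrix(FALSE, nrow(image), ncol(image)))
  lab <- label_mask(weak, 8L)
  keep_ids <- unique(lab[strong])
  matrix(lab %in% keep_ids[keep_ids > 0L], nrow(image), ncol(image))
}

# block-mean downsampling by an integer factor (pyramid step)
downsample_mean <- function(image, factor) {
  if (factor == 1L) return(image)
  nr <- nrow(image); nc <- ncol(image)
  ri <- ceiling(seq_len(nr) / factor)
  ci <- ceiling(seq_len(nc) / factor)
  sums <- rowsum(t(rowsum(image, ri)), ci)
  cnts <- rowsum(t(rowsum(matrix(1, nr, nc), ri)), ci)
  t(sums / cnts)
}

# nearest-neighbor upsampling back to a target shape
upsample_nearest <- function(small, nr, nc, factor) {
  ri <- pmin(ceiling(seq_len(nr) / factor), nrow(small))
  ci <- pmin(ceiling(seq_len(nc) / factor), ncol(small))
  small[ri, ci, drop = FALSE]
}

#' Multi-scale Canny edge maps merged at full resolution
#'
#' Runs Canny on the original image and on 1/2- and 1/4-downsampled copies,
#' upsamples each binary map back to full resolution by nearest neighbor,
#' and merges them by logical OR (the binary realization of summing the
#' per-scale maps). Coarse scales thicken edge coverage, which makes the
#' downstream ROI mask more permissive.
#'
#' @param image Numeric matrix in \[0,1\]; the 1/4-scale copy must be at
#'   least 8x8.
#' @param sigma,low,high Canny parameters applied at every scale (see
#'   [canny_edges()]).
#' @param scales Integer downsampling factors.
#' @return An object of class `hma_edges`: list with `per_scale` (named list
#'   of full-resolution logical maps) and `merged`.
#' @export
multiscale_edge_map <- function(image, sigma = 1.0, low = NULL, high = NULL,
                                scales = c(1L, 2L, 4L)) {
  image <- check_intensity_image(image)
  nr <- nrow(image); nc <- ncol(image)
  if (floor(nr / max(scales)) < 8 || floor(nc / max(scales)) < 8)
    stop("image too small: the coarsest scale must be at least 8x8", call. = FALSE)
  per_scale <- list()
  merged <- matrix(FALSE, nr, nc)
  for (f in as.integer(scales)) {
    small <- downsample_mean(image, f)
    e <- canny_edges(small, sigma = sigma, low = low, high = high)
    full <- upsample_nearest(e, nr, nc, f)
    per_scale[[paste0("1/", f)]] <- full
    merged <- merged | full
  }
  structure(list(per_scale = per_scale, merged = merged), class = "hma_edges")
}

#' Build the maximum ROI mask from merged edge maps
#'
#' Morphological flow: binary closing (disk), hole filling, erosion (disk),
#' area opening, then 8-connected labeling. The result is deliberately
#' permissive — it should cover every cell event even at the price of
#' including background, because each region is thresholded locally later.
#'
#' @param edges An `hma_edges` object (or a logical matrix used as the
#'   merged map).
#' @param close_radius,erode_radius Disk radii in pixels.
#' @param min_region_area Minimum region area in pixels kept by the area
#'   opening.
#' @return An object of class `hma_roi`: list with `mask` (logical),
#'   `labels` (integer matrix of 8-connected region ids) and `n` regions.
#' @export
build_max_roi <- function(edges, close_radius = 3L, erode_radius = 2L,
                          min_region_area = 500L) {
  merged <- if (inherits(edges, "hma_edges")) edges$merged else edges
  stopifnot(is.matrix(merged))
  m <- binary_close(merged > 0, close_radius)
  m <- fill_holes(m)
  m <- binary_erode(m, erode_radius)
  m <- area_open(m, min_region_area, 8L)
  labels <- label_mask(m, 8L)
  structure(list(mask = m, labels = labels, n = max(labels)), class = "hma_roi")
}

#' @exportS3Method base::print
print.hma_roi <- function(x, ...) {
  cat("maximum ROI mask:", nrow(x$mask), "x", ncol(x$mask), "px,",
      x$n, "regions,", sum(x$mask), "foreground pixels\n")
  invisible(x)
}

#' One-call ROI computation
#'
#' Convenience wrapper: [multiscale_edge_map()] followed by
#' [build_max_roi()] using the parameters in `config$roi`.
#'
#' @param image Numeric matrix in \[0,1\].
#' @param config A configuration list from [hma_config()].
#' @return An `hma_roi` object.
#' @export
compute_roi <- function(image, config = hma_config()) {
  p <- config$roi
  edges <- multiscale_edge_map(image, sigma = p$canny_sigma,
                               low = p$canny_low, high = p$canny_high,
                               scales = p$scales)
  build_max_roi(edges, close_radius = p$close_radius,
                erode_radius = p$erode_radius,
                min_region_area = p$min_region_area)
}
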