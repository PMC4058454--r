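# Synthetic phase-contrast scenes with per-cell ground truth. The generator
# realizes, measurably, the image properties the pipeline exploits: cell
# interiors share the background mean gray level (shade-off) but carry
# dense zero-mean speckle (intracellular structure, high local gradient);
# a bright halo ring hugs each cell boundary; the background is smooth; a
# controllable fraction of cells adhere to a neighbor. It does not model
# phase-contrast optics (no point-spread function) — it is a measurable
# stand-in for unavailable real sequences, not a physical simulation.

#' Parameters of a synthetic phase-contrast scene
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 512 x 512 frames holding 20 cells of radius 22-34 px (mitotic
#' cells smaller and rounder, apoptotic cells smaller and more irregular),
#' 30% of cells adhering to a neighbor, halo amplitude 0.25 above the
#' background mean, intracellular speckle sd 0.08 against background noise
#' sd 0.02 (the background must be smoother than cell interiors).
#'
#' @param height,width Frame size in pixels.
#' @param n_cells Number of cells to place.
#' @param adhesion_fraction Fraction of cells placed touching a neighbor.
#' @param halo_gain Brightness of the 2-px boundary ring above background.
#' @param speckle_sd Intracellular texture amplitude (gray levels).
#' @param background_sd Background noise amplitude; must be below
#'   `speckle_sd`.
#' @param background_mean Background gray level on \[0,1\].
#' @param radius_range Base cell radius range in pixels.
#' @param stage_mix Probabilities over the stages normal, mitosis,
#'   apoptosis.
#' @return A list of class `hma_scene_params`.
#' @export
scene_params <- function(height = 512L, width = 512L, n_cells = 20L,
                         adhesion_fraction = 0.3, halo_gain = 0.25,
                         speckle_sd = 0.08, background_sd = 0.02,
                         background_mean = 0.45,
                         radius_range = c(22, 34),
                         stage_mix = c(normal = 0.8, mitosis = 0.1,
                                       apoptosis = 0.1)) {
  if (background_sd >= speckle_sd)
    stop("background_sd must be below speckle_sd (background smoother than cells)",
         call. = FALSE)
  if (adhesion_fraction < 0 || adhesion_fraction > 1)
    stop("adhesion_fraction must be in [0,1]", call. = FALSE)
  stage_mix <- stage_mix / sum(stage_mix)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 adhesion_fraction = adhesion_fraction,
                 halo_gain = halo_gain, speckle_sd = speckle_sd,
                 background_sd = background_sd,
                 background_mean = background_mean,
                 radius_range = radius_range, stage_mix = stage_mix),
            class = "hma_scene_params")
}

# stage-dependent shape/intensity modifiers
stage_profile <- function(stage) {
  switch(stage,
    normal    = list(r_scale = 1.00, e = c(0.05, 0.20), a = c(0.00, 0.08),
                     bias = -0.03),
    mitosis   = list(r_scale = 0.65, e = c(0.00, 0.05), a = c(0.00, 0.03),
                     bias = +0.04),
    apoptosis = list(r_scale = 0.75, e = c(0.10, 0.25), a = c(0.05, 0.15),
                     bias = -0.04))
}

# boundary radius of a deformed ellipse at polar angle theta
cell_radius_at <- function(cell, theta) {
  cell$r0 * (1 + cell$e * cos(2 * (theta - cell$phi))) *
    (1 + cell$a3 * cos(3 * theta + cell$p3) + cell$a4 * cos(4 * theta + cell$p4))
}

draw_cell_shape <- function(params) {
  stage <- sample(names(params$stage_mix), 1L, prob = params$stage_mix)
  pr <- stage_profile(stage)
  r0 <- runif(1, params$radius_range[1], params$radius_range[2]) * pr$r_scale
  list(r0 = r0,
       e = runif(1, pr$e[1], pr$e[2]), phi = runif(1, 0, pi),
       a3 = runif(1, pr$a[1], pr$a[2]), p3 = runif(1, 0, 2 * pi),
       a4 = runif(1, pr$a[1], pr$a[2]), p4 = runif(1, 0, 2 * pi),
       stage = stage, bias = pr$bias)
}

# conservative outer radius bound for clearance tests
cell_rmax <- function(cell) cell$r0 * (1 + cell$e + cell$a3 + cell$a4)

draw_placement <- function(params) {
  n <- params$n_cells
  cells <- vector("list", n)
  if (n == 0L) return(cells)
  n_adh <- round(params$adhesion_fraction * n)
  adhesive <- rep(FALSE, n)
  if (n_adh > 0 && n >= 2)
    adhesive[sample(2:n, min(n_adh, n - 1L))] <- TRUE
  for (i in seq_len(n)) {
    shape <- draw_cell_shape(params)
    rmax <- cell_rmax(shape)
    placed <- FALSE
    for (try in seq_len(400L)) {
      if (adhesive[i] && i > 1L) {
        j <- sample(i - 1L, 1L)
        host <- cells[[j]]
        ang <- runif(1, 0, 2 * pi)
        d <- cell_radius_at(host, ang) + cell_radius_at(shape, ang + pi) - 1.5
        row <- host$row + d * sin(ang)
        col <- host$col + d * cos(ang)
        shape$attached_to <- j
      } else {
        row <- runif(1, rmax + 3, params$height - rmax - 3)
        col <- runif(1, rmax + 3, params$width - rmax - 3)
        shape$attached_to <- NA_integer_
      }
      if (row < rmax + 2 || row > params$height - rmax - 2 ||
          col < rmax + 2 || col > params$width - rmax - 2) next
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (adhesive[i] && identical(j, shape$attached_to)) next
        dj <- sqrt((cells[[j]]$row - row)^2 + (cells[[j]]$col - col)^2)
        lim <- cell_rmax(cells[[j]]) + rmax + (if (adhesive[i]) -2 else 4)
        if (dj < lim) { ok <- FALSE; break }
      }
      if (ok) {
        shape$row <- row; shape$col <- col
        cells[[i]] <- shape
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cell ", i, " after bounded retries; ",
           "reduce n_cells or enlarge the frame", call. = FALSE)
  }
  cells
}

# rasterize cell outlines into a ground-truth label map; earlier cells keep
# overlapping pixels
rasterize_cells <- function(cells, params, offsets = NULL) {
  gt <- matrix(0L, params$height, params$width)
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    row <- cell$row + if (is.null(offsets)) 0 else offsets[i, 1]
    col <- cell$col + if (is.null(offsets)) 0 else offsets[i, 2]
    rmax <- ceiling(cell_rmax(cell)) + 1L
    r1 <- max(1L, floor(row - rmax)); r2 <- min(params$height, ceiling(row + rmax))
    c1 <- max(1L, floor(col - rmax)); c2 <- min(params$width, ceiling(col + rmax))
    dr <- outer(r1:r2 - row, rep(1, c2 - c1 + 1L))
    dc <- outer(rep(1, r2 - r1 + 1L), c1:c2 - col)
    dist <- sqrt(dr^2 + dc^2)
    theta <- atan2(dr, dc)
    inside <- dist <= cell_radius_at(cell, theta)
    sub <- gt[r1:r2, c1:c2, drop = FALSE]
    claim <- inside & sub == 0L
    sub[claim] <- i
    gt[r1:r2, c1:c2] <- sub
  }
  gt
}

validate_raster <- function(gt, cells, min_area = 30L) {
  for (i in seq_along(cells)) {
    m <- gt == i
    if (sum(m) < min_area) return(FALSE)
    if (max(label_mask(m, 8L)) != 1L) return(FALSE)
    j <- cells[[i]]$attached_to
    if (!is.na(j)) {
      touch <- binary_dilate(m, 1L) & gt == j
      if (!any(touch)) return(FALSE)
    }
  }
  TRUE
}

render_scene_image <- function(gt, cells, params) {
  img <- params$background_mean +
    matrix(rnorm(length(gt), 0, params$background_sd), nrow(gt), ncol(gt))
  for (i in seq_along(cells)) {
    m <- gt == i
    ring <- m & !binary_erode(m, 2L)
    interior <- m & !ring
    ni <- sum(interior); nr <- sum(ring)
    img[interior] <- params$background_mean + cells[[i]]$bias +
      rnorm(ni, 0, params$speckle_sd)
    img[ring] <- params$background_mean + params$halo_gain +
      rnorm(nr, 0, params$speckle_sd / 2)
  }
  pmin(pmax(img, 0), 1)
}

make_cell_records <- function(gt, cells) {
  if (length(cells) == 0L)
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area = integer(0),
                      stage = character(0)))
  px <- which(gt > 0L)
  lab <- gt[px]
  rows <- ((px - 1L) %% nrow(gt)) + 1L
  cols <- ((px - 1L) %/% nrow(gt)) + 1L
  data.frame(
    label = seq_along(cells),
    centroid_row = as.numeric(tapply(rows, factor(lab, seq_along(cells)), mean)),
    centroid_col = as.numeric(tapply(cols, factor(lab, seq_along(cells)), mean)),
    area = as.integer(tabulate(lab, length(cells))),
    stage = vapply(cells, `[[`, "", "stage"))
}

.generate_scene_impl <- function(params, seed) {
  cells <- NULL
  gt <- NULL
  for (attempt in seq_len(25L)) {
    cells <- draw_placement(params)
    gt <- rasterize_cells(cells, params)
    if (validate_raster(gt, cells)) break
    cells <- NULL
  }
  if (is.null(cells) && params$n_cells > 0L)
    stop("could not realize a valid scene after bounded retries", call. = FALSE)
  if (params$n_cells == 0L) gt <- matrix(0L, params$height, params$width)
  img <- render_scene_image(gt, cells, params)
  structure(list(image = img, gt_labels = gt,
                 cell_records = make_cell_records(gt, cells),
                 cells = cells, seed = seed, params = params),
            class = "hma_scene")
}

#' Generate a synthetic phase-contrast scene
#'
#' Draws a reproducible scene: same `(params, seed)` always yields a
#' bit-identical image and ground truth. Cells are deformed ellipses whose
#' interior mean matches the background (within the per-stage bias of at
#' most 0.04 gray levels), with an additive bright 2-px halo ring, zero-mean
#' interior speckle, and Gaussian background noise.
#'
#' @param params A [scene_params()] list.
#' @param seed Integer seed driving all randomness of the scene.
#' @return An object of class `hma_scene`: list with `image` (numeric
#'   matrix in \[0,1\]), `gt_labels` (integer matrix, one positive label per
#'   cell), `cell_records` (data frame: label, centroid, area, stage),
#'   `seed` and `params`.
#' @examples
#' sc <- generate_scene(scene_params(n_cells = 3, height = 128, width = 128,
#'                                   radius_range = c(12, 16)), seed = 1)
#' nrow(sc$cell_records)
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  with_seed(seed, .generate_scene_impl(params, seed))
}

#' Generate a jittered sequence of scenes
#'
#' Frames share one cell placement; from frame 2 on, every cell performs a
#' bounded random walk (steps uniform in ±1 px per axis, total drift clamped
#' to ±4 px), so consecutive-frame centroid displacement stays small. Frame
#' 1 is identical to `generate_scene(params, seed)`.
#'
#' @param params A [scene_params()] list.
#' @param n_frames Number of frames (at least 1).
#' @param seed Integer seed.
#' @return List of `hma_scene` objects.
#' @export
generate_sequence <- function(params = scene_params(), n_frames = 3L, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be at least 1", call. = FALSE)
  first <- generate_scene(params, seed)
  frames <- vector("list", n_frames)
  frames[[1]] <- first
  if (n_frames == 1L) return(frames)
  fseeds <- derive_seeds(seed + 1L, n_frames)
  offsets <- matrix(0, length(first$cells), 2L)
  for (f in 2:n_frames) {
    frames[[f]] <- with_seed(fseeds[f], {
      step <- matrix(runif(length(first$cells) * 2L, -1, 1),
                     ncol = 2L)
      offsets <- pmin(pmax(offsets + step, -4), 4)
      gt <- rasterize_cells(first$cells, params, offsets = offsets)
      img <- render_scene_image(gt, first$cells, params)
      structure(list(image = img, gt_labels = gt,
                     cell_records = make_cell_records(gt, first$cells),
                     cells = first$cells, seed = fseeds[f], params = params),
                class = "hma_scene")
    })
  }
  frames
}

#' Export a scene to disk
#'
#' Writes the image as 16-bit TIFF, the ground truth as a 16-bit TIFF label
#' map, and the cell records as JSON lines.
#'
#' @param scene An `hma_scene`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stopifnot(inherits(scene, "hma_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(prefix, "_image.tif"))
  gt_path <- file.path(dir, paste0(prefix, "_gt.tif"))
  rec_path <- file.path(dir, paste0(prefix, "_cells.jsonl"))
  tiff::writeTIFF(round(scene$image * 65535) / 65535, img_path,
                  bits.per.sample = 16L, compression = "none")
  write_label_map(scene$gt_labels, gt_path)
  con <- file(rec_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(scene$cell_records)))
    writeLines(jsonlite::toJSON(as.list(scene$cell_records[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(c(image = img_path, gt = gt_path, records = rec_path))
}

#' @exportS3Method base::print
print.hma_scene <- function(x, ...) {
  cat("synthetic phase-contrast scene:", nrow(x$image), "x", ncol(x$image),
      "px,", nrow(x$cell_records), "cells (seed", x$seed, ")\n")
  invisible(x)
}
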