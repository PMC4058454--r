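# End-to-end pipeline: ROI -> reference stack -> local partition ->
# hierarchical extraction/mergence -> watershed split -> SVM filter, with a
# serializable configuration and reproducible outputs.

#' The composite mergence strategy
#'
#' The default raw result merges the dark section, the interior holes of
#' the bright/prone-bright sub-sections of both bright sections, and the
#' dark (and prone-dark) sub-sections of the bright sections:
#' `A1, (A3A3 u A3A4)holes, A3A1, (A4A3 u A4A4)holes, A4A1, A4A2`.
#'
#' @return The strategy expression string.
#' @export
composite_strategy <- function() {
  paste0("union(sel(1), holes(union(sel(3.3), sel(3.4))), sel(3.1), ",
         "holes(union(sel(4.3), sel(4.4))), sel(4.1), sel(4.2))")
}

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their documented defaults:
#' Canny smoothing sigma 1.0 with automatic hysteresis thresholds at scales
#' 1, 1/2, 1/4; ROI morphology close radius 3, erode radius 2, minimum
#' region area 500 px; blur level n = 20 with sigma 1.0 and kernel radius 5,
#' plus a grayscale-morphology layer; three Otsu thresholds per region;
#' watershed marker separation 24 px with markers required to reach half
#' their component's peak depth; recursion depth capped at 3; hole-layer
#' dilation off (when enabled it preserves patch separation); candidate
#' patches grown 3 px within the ROI after splitting. The level-1
#' partition reads the `gauss20` reference; depth-2 re-partitions read
#' `graymorph`; depth-3 the original.
#'
#' @param ... Named overrides for any nested field, e.g.
#'   `roi = list(min_region_area = 200)`.
#' @return Nested configuration list of class `hma_config`; fully
#'   serializable to JSON.
#' @export
hma_config <- function(...) {
  cfg <- list(
    roi = list(canny_sigma = 1.0, canny_low = NULL, canny_high = NULL,
               scales = c(1L, 2L, 4L), close_radius = 3L, erode_radius = 2L,
               min_region_area = 500L),
    blur = list(layers = default_reference_layers()),
    partition = list(k = 3L, min_seed_distance = 24, relative_depth = 0.5),
    hierarchy = list(base_layer = "gauss20",
                     layer_bindings = c("graymorph", "original"),
                     dilate_holes = 0L, min_fragment = 20L,
                     grow_patches = 3L),
    strategies = composite_strategy(),
    pick = 1L,
    classify = list(min_overlap = 0.5),
    seed = 1L
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      for (sub in names(overrides[[nm]])) cfg[[nm]][[sub]] <- overrides[[nm]][[sub]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = c("hma_config", "list"))
}

# which raw result to carry forward: an index, or "auto" for the heuristic
# solidity-based score
pick_raw_index <- function(results, config) {
  if (identical(config$pick, "auto")) {
    scores <- vapply(results, score_raw_result, 0)
    which.max(scores)
  } else {
    i <- as.integer(config$pick)
    if (i < 1 || i > length(results)) 1L else i
  }
}

# opt-in heuristic: mean patch solidity times the count of patches in a
# plausible area band (removes degenerate all-or-nothing strategies)
score_raw_result <- function(raw) {
  lab <- label_mask(raw$mask, 8L)
  n <- max(lab)
  if (n == 0L) return(0)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  px <- which(lab > 0L)
  rows <- ((px - 1L) %% nrow(lab)) + 1L
  cols <- ((px - 1L) %/% nrow(lab)) + 1L
  sol <- vapply(seq_len(n), function(id) {
    sel <- lab[px] == id
    areas[id] / max(convex_hull_area(rows[sel], cols[sel]), areas[id])
  }, 0)
  plausible <- sum(areas >= 100 & areas <= 20000)
  mean(sol) * plausible
}

#' Run the full detection pipeline on one image
#'
#' Executes every stage in order, optionally filters candidate patches with
#' a trained model, and optionally evaluates against ground truth. When
#' `out_dir` is given, every intermediate layer is written next to a
#' `config.json` capturing the exact configuration (masks as PNG, label
#' maps as 16-bit TIFF, provenance as JSON).
#'
#' @param image Numeric matrix in \[0,1\], an `hma_scene`, or a file path.
#' @param config Configuration from [hma_config()].
#' @param model Optional `hma_filter_model`; without it the unfiltered
#'   candidates are the final result.
#' @param gt Optional ground-truth label matrix for evaluation.
#' @param out_dir Optional output directory.
#' @param verbose Print per-stage progress.
#' @return List of class `hma_result`: `roi`, `refstack`, `raw_results`,
#'   `picked` (index), `labels_raw` (candidates), `labels_final`,
#'   `features`, `report` (if `gt` given) and `config`.
#' @export
run_pipeline <- function(image, config = hma_config(), model = NULL,
                         gt = NULL, out_dir = NULL, verbose = FALSE) {
  if (is.character(image)) image <- read_grayscale(image)
  if (inherits(image, "hma_scene")) {
    if (is.null(gt)) gt <- image$gt_labels
    image <- image$image
  }
  image <- check_intensity_image(image)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(nm, code) {
    t1 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e)
      stop("pipeline stage '", nm, "': ", conditionMessage(e), call. = FALSE))
    say("stage %-10s %6.2fs", nm, proc.time()[["elapsed"]] - t1)
    out
  }
  roi <- stage("roi", compute_roi(image, config))
  refstack <- stage("blur", build_reference_stack(image, config$blur$layers))
  raw_results <- stage("hierarchy",
                       run_strategies(image, config$strategies, config,
                                      roi = roi, refstack = refstack))
  picked <- pick_raw_index(raw_results, config)
  labels_raw <- stage("split", {
    labs <- split_raw(raw_results[[picked]],
                      config$partition$min_seed_distance,
                      config$partition$relative_depth)
    grow_labels(labs, config$hierarchy$grow_patches, roi$mask)
  })
  features <- stage("features", compute_features(labels_raw, image))
  labels_final <- if (!is.null(model)) {
    stage("filter", filter_patches(labels_raw, features, model))
  } else labels_raw
  report <- if (!is.null(gt))
    match_cells(labels_final, gt, config$classify$min_overlap) else NULL
  say("pipeline done in %.2fs", proc.time()[["elapsed"]] - t0)
  res <- structure(list(roi = roi, refstack = refstack,
                        raw_results = raw_results, picked = picked,
                        labels_raw = labels_raw, features = features,
                        labels_final = labels_final, report = report,
                        config = config),
                   class = "hma_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, image, out_dir)
  res
}

write_pipeline_outputs <- function(res, image, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(res$roi$mask, file.path(out_dir, "roi_mask.png"))
  for (nm in names(res$refstack))
    tiff::writeTIFF(round(res$refstack[[nm]]$image * 65535) / 65535,
                    file.path(out_dir, paste0("ref_", nm, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  for (i in seq_along(res$raw_results))
    write_mask(res$raw_results[[i]]$mask,
               file.path(out_dir, sprintf("raw_%02d.png", i)))
  write_label_map(res$labels_raw, file.path(out_dir, "labels_raw.tif"))
  write_label_map(res$labels_final, file.path(out_dir, "labels_final.tif"))
  cfg <- res$config
  cfg$provenance <- list(
    picked = res$picked,
    n_candidates = max(res$labels_raw),
    n_final = max(res$labels_final))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)
  invisible(out_dir)
}

#' @exportS3Method base::print
print.hma_result <- function(x, ...) {
  cat("hierarchical mergence result:", max(x$labels_final), "cells detected",
      "(", max(x$labels_raw), "candidates before filtering )\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
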