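# Local multilevel Otsu. Frames along a sequence contain different ratios
# of gray levels, so one global threshold set cannot serve all images; each
# 8-connected ROI region is instead partitioned independently into four
# intensity sections: dark (A1), prone-dark (A2), bright (A3), prone-bright
# (A4). Thresholds maximize the between-class variance of a 256-bin
# histogram, found by exhaustive search.

N_BINS <- 256L

# bin index in 1..256 for values on [0,1]; bins are left-open, (T-1)/256 <
# v <= T/256, with 0 falling in bin 1, so "v <= T/256" == "bin(v) <= T"
intensity_bin <- function(v) {
  pmin(pmax(ceiling(v * N_BINS), 1L), N_BINS)
}

#' Multilevel Otsu thresholds by exhaustive search
#'
#' Chooses `k` thresholds maximizing the between-class variance over a
#' 256-bin histogram of the values, by exhaustive search over all ordered
#' threshold tuples (with cumulative class moments, so the k = 3 case scans
#' about 2.7 million triples exactly). Ties are broken by the
#' lexicographically smallest tuple. Each threshold is reported as the upper
#' edge of its bin, so a value `v` belongs to the class below threshold `t`
#' iff `v <= t`.
#'
#' @param values Numeric vector of intensities in \[0,1\].
#' @param k Number of thresholds (1, 2 or 3).
#' @return Sorted numeric vector of `k` thresholds in (0,1).
#' @examples
#' v <- c(rep(0.05, 50), rep(0.35, 50), rep(0.65, 50), rep(0.95, 50))
#' multilevel_otsu(v, k = 3)
#' @export
multilevel_otsu <- function(values, k = 3L) {
  k <- as.integer(k)
  if (!k %in% 1:3) stop("k must be 1, 2 or 3", call. = FALSE)
  values <- values[is.finite(values)]
  if (length(unique(values)) < k + 1)
    stop_degenerate("fewer than k+1 distinct values")
  if (any(values < 0 | values > 1))
    stop("values must lie in [0,1]", call. = FALSE)
  counts <- tabulate(intensity_bin(values), nbins = N_BINS)
  bins <- otsu_thresholds_cpp(counts, k)
  bins / N_BINS
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("hma_degenerate_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Per-region multilevel Otsu classification
#'
#' Applies [multilevel_otsu()] independently to each 8-connected ROI region
#' using that region's reference intensities, then bins every region pixel
#' into classes 1 (dark) through `k + 1` (bright). Regions with fewer than
#' `k + 1` distinct reference values are mapped wholly to class 1 instead of
#' aborting the run.
#'
#' @param reference Numeric matrix in \[0,1\] (a reference layer).
#' @param roi An `hma_roi` object, or any list with logical `mask` and
#'   integer `labels` of the same shape as `reference`.
#' @param k Number of thresholds per region (default 3, giving 4 classes).
#' @return An object of class `hma_classmap`: list with `labels` (integer
#'   matrix, 0 outside the ROI), `thresholds` (named list, region id to
#'   sorted threshold vector, `NULL` for degenerate regions) and `k`.
#' @export
local_otsu_classify <- function(reference, roi, k = 3L) {
  reference <- as_numeric_matrix(reference, "reference")
  region_labels <- if (inherits(roi, "hma_roi") || is.list(roi)) roi$labels else roi
  if (!all(dim(reference) == dim(region_labels)))
    stop("reference and ROI shapes differ", call. = FALSE)
  out <- matrix(0L, nrow(reference), ncol(reference))
  thresholds <- list()
  n <- max(region_labels, 0L)
  if (n > 0L) {
    pix_by_region <- split(which(region_labels > 0L),
                           region_labels[region_labels > 0L])
    for (id in names(pix_by_region)) {
      px <- pix_by_region[[id]]
      v <- reference[px]
      thr <- tryCatch(multilevel_otsu(v, k = k),
                      hma_degenerate_error = function(e) NULL)
      if (is.null(thr)) {
        out[px] <- 1L
        thresholds[[id]] <- NULL
      } else {
        cls <- rep(1L, length(v))
        for (t in thr) cls <- cls + (v > t)
        out[px] <- cls
        thresholds[[id]] <- thr
      }
    }
  }
  structure(list(labels = out, thresholds = thresholds, k = k),
            class = "hma_classmap")
}

#' Select classes from a class map as a binary mask
#'
#' @param cm An `hma_classmap`.
#' @param classes Integer vector of class ids within `1..(k+1)`.
#' @return Logical matrix, true where the pixel class is in `classes`.
#' @export
class_select <- function(cm, classes) {
  stopifnot(inherits(cm, "hma_classmap"))
  classes <- as.integer(classes)
  if (length(classes) > 0 && !all(classes %in% seq_len(cm$k + 1L)))
    stop("class ids must be in 1..", cm$k + 1L, call. = FALSE)
  matrix(cm$labels %in% classes, nrow(cm$labels), ncol(cm$labels))
}

#' Marker-controlled watershed splitting of a binary mask
#'
#' Splits adherent patches: markers are local maxima of the Euclidean
#' distance transform, thinned twice — maxima shallower than
#' `relative_depth` times the deepest maximum of their connected component
#' are discarded (they sit on boundary lobes, not cell bodies), and the
#' survivors are kept only if at least `min_seed_distance` from any deeper
#' marker. Regions are then grown over the negated distance transform.
#' Every true pixel of the mask receives exactly one label and every
#' label's support is 8-connected.
#'
#' @param mask Logical matrix.
#' @param min_seed_distance Minimum marker separation in pixels.
#' @param relative_depth Minimum marker depth as a fraction of its
#'   component's maximum depth, in \[0,1\].
#' @return Integer label matrix (0 = background), labels `1..n` with no gaps.
#' @export
watershed_split <- function(mask, min_seed_distance = 10,
                            relative_depth = 0.5) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask))
    return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask * 1)
  d <- as.matrix(d)
  # plateau-tolerant local maxima of the distance transform
  dmax <- EBImage::dilate(d, disk_brush(2L))
  cand <- mask & d >= as.matrix(dmax) - 1e-9
  # suppress maxima on shallow boundary lobes
  if (relative_depth > 0) {
    comp <- label_mask(mask, 8L)
    peak <- rep(0, max(comp))
    cpx <- which(cand)
    for (i in cpx) peak[comp[i]] <- max(peak[comp[i]], d[i])
    cand[cpx] <- d[cpx] >= relative_depth * peak[comp[cpx]]
  }
  cand_lab <- label_mask(cand, 8L)
  ncand <- max(cand_lab)
  if (ncand == 0L) {
    lab <- label_mask(mask, 8L)
    return(renumber_labels(lab))
  }
  px <- which(cand_lab > 0L)
  comp <- cand_lab[px]
  rows <- ((px - 1L) %% nrow(mask)) + 1L
  cols <- ((px - 1L) %/% nrow(mask)) + 1L
  cr <- vapply(split(rows, comp), function(z) mean(z), 0)
  cc <- vapply(split(cols, comp), function(z) mean(z), 0)
  depth <- vapply(split(d[px], comp), max, 0)
  ord <- order(-depth, cr, cc)
  keep_r <- numeric(0); keep_c <- numeric(0)
  for (i in ord) {
    if (length(keep_r) == 0 ||
        min(sqrt((keep_r - cr[i])^2 + (keep_c - cc[i])^2)) >= min_seed_distance) {
      keep_r <- c(keep_r, cr[i]); keep_c <- c(keep_c, cc[i])
    }
  }
  seeds <- matrix(0L, nrow(mask), ncol(mask))
  sr <- pmin(pmax(round(keep_r), 1), nrow(mask))
  sc <- pmin(pmax(round(keep_c), 1), ncol(mask))
  seeds[cbind(sr, sc)] <- seq_along(sr)
  lab <- EBImage::propagate(max(d) - d, seeds = seeds, mask = mask)
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  # propagate can miss pixels disconnected from every seed; give each
  # remaining 8-connected piece its own label
  rest <- mask & lab == 0L
  if (any(rest)) {
    extra <- label_mask(rest, 8L)
    lab[rest] <- extra[rest] + max(lab)
  }
  # enforce 8-connectivity of each label's support
  split_disconnected_labels(renumber_labels(lab))
}

split_disconnected_labels <- function(lab) {
  n <- max(lab, 0L)
  if (n == 0L) return(lab)
  out <- lab
  nxt <- n
  for (id in seq_len(n)) {
    m <- lab == id
    comp <- label_mask(m, 8L)
    nc <- max(comp)
    if (nc > 1L) {
      for (j in 2:nc) {
        nxt <- nxt + 1L
        out[comp == j] <- nxt
      }
    }
  }
  renumber_labels(out)
}

#' @exportS3Method base::print
print.hma_classmap <- function(x, ...) {
  cat("local Otsu class map:", x$k, "thresholds,",
      length(x$thresholds), "non-degenerate regions,",
      sum(x$labels > 0L), "classified pixels\n")
  invisible(x)
}
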