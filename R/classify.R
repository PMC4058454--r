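# Patch filtering. The raw mergence result contains redundant non-cell
# patches; each watershed-split candidate patch is described by
# morphological, intensity and local-binary-pattern features and screened
# by a support vector machine trained on synthetic scenes (a candidate is a
# positive example iff at least half of its pixels fall inside one
# ground-truth cell).

#' Split a raw result into candidate cell patches
#'
#' Applies [watershed_split()] to the raw mask; the resulting labels are the
#' candidate cells submitted to the patch filter.
#'
#' @param raw An `hma_raw` result (or a logical mask).
#' @param min_seed_distance Marker separation in pixels.
#' @param relative_depth Marker depth floor (see [watershed_split()]).
#' @param absorb_area,absorb_distance Fragments smaller than `absorb_area`
#'   pixels lying within `absorb_distance` pixels of a larger patch are
#'   merged into the nearest such patch (halo-flank arcs broken off a cell
#'   body rejoin it); set `absorb_area = 0` to disable.
#' @return Integer label matrix.
#' @export
split_raw <- function(raw, min_seed_distance = 10, relative_depth = 0.5,
                      absorb_area = 500, absorb_distance = 3) {
  mask <- if (inherits(raw, "hma_raw")) raw$mask else raw
  labs <- watershed_split(mask, min_seed_distance, relative_depth)
  if (absorb_area > 0)
    labs <- absorb_fragments(labs, absorb_area, absorb_distance)
  labs
}

# merge each patch smaller than absorb_area into the neighboring larger
# patch with the longest shared (dilated) frontier, if one lies within
# absorb_distance; larger patches are never merged with each other
absorb_fragments <- function(labels, absorb_area, absorb_distance) {
  n <- max(labels, 0L)
  if (n == 0L) return(labels)
  areas <- tabulate(labels[labels > 0L], nbins = n)
  small <- which(areas > 0 & areas < absorb_area)
  if (length(small) == 0L) return(labels)
  out <- labels
  for (id in small[order(areas[small])]) {
    m <- out == id
    if (!any(m)) next
    near <- hmacell_dilate_ids(m, absorb_distance, out, id)
    if (length(near) == 0L) next
    # prefer the largest eligible neighbor
    sizes <- tabulate(out[out > 0L], nbins = max(out))
    cand <- near[sizes[near] >= absorb_area]
    if (length(cand) == 0L) next
    host <- cand[which.max(sizes[cand])]
    out[m] <- host
  }
  renumber_labels(out)
}

# labels of other patches overlapped by the dilation of m (bounding-box
# windowed for speed)
hmacell_dilate_ids <- function(m, radius, labels, self) {
  px <- which(m)
  rows <- ((px - 1L) %% nrow(m)) + 1L
  cols <- ((px - 1L) %/% nrow(m)) + 1L
  r1 <- max(1L, min(rows) - radius); r2 <- min(nrow(m), max(rows) + radius)
  c1 <- max(1L, min(cols) - radius); c2 <- min(ncol(m), max(cols) + radius)
  sub <- m[r1:r2, c1:c2, drop = FALSE]
  grown <- binary_dilate(sub, radius)
  ids <- labels[r1:r2, c1:c2, drop = FALSE][grown]
  setdiff(unique(ids[ids > 0L]), self)
}

# rotation-invariant uniform LBP (P = 8 neighbors, R = 1): patterns with at
# most two 0/1 transitions are binned by their number of set bits (bins
# 1..9 for 0..8 ones), all non-uniform codes share bin 10
lbp_code_table <- function() {
  codes <- 0:255
  bits <- t(sapply(codes, function(x) as.integer(intToBits(x)[1:8])))
  trans <- rowSums(bits != bits[, c(2:8, 1)])
  ones <- rowSums(bits)
  ifelse(trans <= 2, ones + 1L, 10L)
}

.lbp_env <- new.env(parent = emptyenv())

#' Uniform LBP histogram of a patch
#'
#' Computes the 8-neighbor, radius-1 local binary pattern over the patch's
#' interior pixels (pixels whose 8 neighbors all lie inside the patch mask)
#' and returns the L1-normalized 10-bin rotation-invariant uniform
#' histogram. Patches with no interior pixel fall back to all patch pixels
#' with neighbors read from the surrounding image.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix selecting the patch.
#' @return Numeric vector of 10 histogram bins summing to 1.
#' @export
lbp_histogram <- function(image, mask) {
  if (is.null(.lbp_env$table)) .lbp_env$table <- lbp_code_table()
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, nrow(image), ncol(image))
  inner <- mask
  for (b in seq_along(offs)) {
    nb <- shift_replicate(image, offs[[b]][1], offs[[b]][2])
    code <- code + as.integer(nb >= image) * 2L^(b - 1L)
    inner <- inner & shift_replicate(mask, offs[[b]][1], offs[[b]][2])
  }
  sel <- if (any(inner)) inner else mask
  bins <- .lbp_env$table[code[sel] + 1L]
  h <- tabulate(bins, nbins = 10L)
  h / sum(h)
}

feature_names <- function() {
  c("area", "perimeter", "eccentricity", "solidity", "extent",
    "mean_intensity", "sd_intensity", "mean_gradient",
    paste0("lbp", 1:10))
}

#' Per-patch features for the cell/non-cell filter
#'
#' One row per label: area, perimeter (count of pixel edges facing outside
#' the patch), eccentricity from central moments, solidity (area over
#' convex-hull area), extent (area over bounding-box area), mean and sd of
#' intensity, mean gradient magnitude, and the 10-bin uniform LBP histogram.
#' All features are finite even for single-pixel patches.
#'
#' @param labels Integer label matrix.
#' @param image Numeric intensity matrix of the same shape.
#' @return Data frame with `label` plus the columns of `feature_names()`.
#' @export
compute_features <- function(labels, image) {
  image <- as_numeric_matrix(image)
  if (!all(dim(labels) == dim(image)))
    stop("labels and image shapes differ", call. = FALSE)
  if (is.null(.lbp_env$table)) .lbp_env$table <- lbp_code_table()
  n <- max(labels, 0L)
  out <- as.data.frame(matrix(NA_real_, n, length(feature_names())))
  names(out) <- feature_names()
  if (n == 0L) return(cbind(label = integer(0), out[0, , drop = FALSE]))
  g <- finite_difference_gradient(image)
  gmag <- matrix(0, nrow(image), ncol(image))
  gmag[seq_len(nrow(image) - 1L), seq_len(ncol(image) - 1L)] <- g$magnitude
  # per-image precomputations shared by all patches: LBP code matrix,
  # patch-interior mask (all 8 neighbors carry the same label) and the
  # per-pixel count of exposed 4-neighbor edges (boundary pixels of the
  # frame count their out-of-frame sides as exposed)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, nrow(image), ncol(image))
  interior <- labels > 0L
  padlab <- matrix(-1L, nrow(labels) + 2L, ncol(labels) + 2L)
  padlab[2:(nrow(labels) + 1L), 2:(ncol(labels) + 1L)] <- labels
  core <- function(m, dr, dc)
    m[(2:(nrow(labels) + 1L)) - dr, (2:(ncol(labels) + 1L)) - dc]
  exposed <- matrix(0L, nrow(labels), ncol(labels))
  for (b in seq_along(offs)) {
    dr <- offs[[b]][1]; dc <- offs[[b]][2]
    nb <- shift_replicate(image, dr, dc)
    code <- code + as.integer(nb >= image) * 2L^(b - 1L)
    same <- core(padlab, dr, dc) == labels
    interior <- interior & same
    if (abs(dr) + abs(dc) == 1L) exposed <- exposed + !same
  }
  lbp_bin <- .lbp_env$table[code + 1L]
  px_all <- which(labels > 0L)
  lab_all <- labels[px_all]
  rows_all <- ((px_all - 1L) %% nrow(labels)) + 1L
  cols_all <- ((px_all - 1L) %/% nrow(labels)) + 1L
  idx_by <- split(seq_along(px_all), lab_all)
  for (id in seq_len(n)) {
    ii <- idx_by[[as.character(id)]]
    r <- rows_all[ii]; cc <- cols_all[ii]; px <- px_all[ii]
    a <- length(r)
    per <- sum(exposed[px])
    mu_r <- mean(r); mu_c <- mean(cc)
    vrr <- mean((r - mu_r)^2) + 1 / 12
    vcc <- mean((cc - mu_c)^2) + 1 / 12
    vrc <- mean((r - mu_r) * (cc - mu_c))
    tr <- vrr + vcc
    det <- sqrt(max((vrr - vcc)^2 + 4 * vrc^2, 0))
    l1 <- (tr + det) / 2; l2 <- max((tr - det) / 2, 1e-12)
    ecc <- sqrt(max(1 - l2 / l1, 0))
    hull_area <- convex_hull_area(r, cc)
    solidity <- min(a / max(hull_area, a), 1)
    extent <- a / ((diff(range(r)) + 1) * (diff(range(cc)) + 1))
    inn <- px[interior[px]]
    if (length(inn) == 0L) inn <- px
    h <- tabulate(lbp_bin[inn], nbins = 10L)
    vals <- image[px]
    out[id, ] <- c(a, per, ecc, solidity, extent,
                   mean(vals), if (a > 1) sd(vals) else 0,
                   mean(gmag[px]),
                   h / sum(h))
  }
  cbind(label = seq_len(n), out)
}

# area of the convex hull of pixel centers, padded by the half-pixel border
convex_hull_area <- function(r, cc) {
  if (length(r) < 3L) return(length(r))
  h <- grDevices::chull(cc, r)
  x <- cc[h]; y <- r[h]
  n <- length(h)
  shoelace <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  # pixel-center hull underestimates the pixelated area; add the boundary band
  shoelace + length(unique(paste(r, cc)[h])) / 2 + 1
}

#' Train the cell/non-cell patch filter
#'
#' Runs the extraction pipeline (without filtering) on each training scene,
#' labels every candidate patch positive iff at least `min_overlap` of its
#' pixels lie inside one ground-truth cell, standardizes the features, and
#' fits an RBF support vector machine. A small hyperparameter grid is
#' scored on the held-out scenes (the last `ceiling(20%)` of the list) and
#' the best model is refit; held-out accuracy is stored in the metadata.
#'
#' @param scenes List of `hma_scene` objects (at least 2).
#' @param config Pipeline configuration from [hma_config()].
#' @param seed Integer seed for the SVM fit.
#' @param min_overlap Fraction of patch pixels that must fall inside one
#'   ground-truth cell for a positive training label.
#' @return An object of class `hma_filter_model`.
#' @export
train_patch_filter <- function(scenes, config = hma_config(), seed = 7L,
                               min_overlap = 0.5) {
  if (length(scenes) < 2L) stop("need at least 2 training scenes", call. = FALSE)
  sets <- lapply(scenes, function(sc) {
    res <- run_strategies(sc$image, config$strategies, config)
    raw <- res[[pick_raw_index(res, config)]]
    labs <- split_raw(raw, config$partition$min_seed_distance,
                      config$partition$relative_depth)
    labs <- grow_labels(labs, config$hierarchy$grow_patches,
                        attr(res, "context")$roi$mask)
    if (max(labs) == 0L) return(NULL)
    feats <- compute_features(labs, sc$image)
    y <- patch_labels(labs, sc$gt_labels, min_overlap)
    cbind(feats, cell = y)
  })
  sets <- Filter(Negate(is.null), sets)
  if (length(sets) < 2L) stop("training scenes produced too few patches", call. = FALSE)
  n_hold <- max(1L, ceiling(length(sets) * 0.2))
  hold <- sets[(length(sets) - n_hold + 1L):length(sets)]
  train <- sets[seq_len(length(sets) - n_hold)]
  tr <- do.call(rbind, train)
  ho <- do.call(rbind, hold)
  if (length(unique(tr$cell)) < 2L)
    stop("training set contains a single class; cannot fit the filter",
         call. = FALSE)
  fn <- feature_names()
  center <- vapply(tr[fn], mean, 0)
  scale <- vapply(tr[fn], function(v) max(sd(v), 1e-8), 0)
  std <- function(df) as.data.frame(sweep(sweep(as.matrix(df[fn]), 2, center), 2, scale, "/"))
  xtr <- std(tr); ytr <- factor(tr$cell, c(0, 1))
  xho <- std(ho); yho <- factor(ho$cell, c(0, 1))
  wts <- c("0" = 1, "1" = 1)
  tab <- table(ytr)
  if (all(tab > 0)) wts <- c("0" = as.numeric(sum(tab) / (2 * tab["0"])),
                             "1" = as.numeric(sum(tab) / (2 * tab["1"])))
  names(wts) <- c("0", "1")
  grid <- expand.grid(cost = c(1, 10, 100),
                      gamma = c(0.5, 1, 2) / length(fn))
  best <- NULL; best_acc <- -1
  for (gi in seq_len(nrow(grid))) {
    fit <- with_seed(seed, e1071::svm(xtr, ytr, kernel = "radial",
                                      cost = grid$cost[gi],
                                      gamma = grid$gamma[gi],
                                      class.weights = wts, scale = FALSE))
    acc <- mean(predict(fit, xho) == yho)
    if (acc > best_acc) { best_acc <- acc; best <- grid[gi, ] }
  }
  all_x <- rbind(xtr, xho); all_y <- factor(c(tr$cell, ho$cell), c(0, 1))
  final <- with_seed(seed, e1071::svm(all_x, all_y, kernel = "radial",
                                      cost = best$cost, gamma = best$gamma,
                                      class.weights = wts, scale = FALSE))
  structure(list(svm = final, center = center, scale = scale,
                 features = fn,
                 meta = list(seed = seed, n_samples = nrow(all_x),
                             n_positive = sum(all_y == "1"),
                             heldout_accuracy = best_acc,
                             cost = best$cost, gamma = best$gamma)),
            class = "hma_filter_model")
}

# overlap-based training labels: 1 iff >= min_overlap of the patch pixels
# lie inside a single ground-truth cell
patch_labels <- function(labels, gt, min_overlap = 0.5) {
  n <- max(labels, 0L)
  y <- integer(n)
  if (n == 0L) return(y)
  px <- which(labels > 0L)
  lab <- labels[px]; g <- gt[px]
  for (id in seq_len(n)) {
    gi <- g[lab == id]
    if (length(gi) == 0L) next
    best <- max(tabulate(gi[gi > 0L], nbins = max(gt)))
    if (length(best) && best / length(gi) >= min_overlap) y[id] <- 1L
  }
  y
}

#' Predict cell/non-cell for candidate patches
#'
#' @param model An `hma_filter_model`.
#' @param features Data frame from [compute_features()].
#' @return Logical vector, `TRUE` for predicted cells.
#' @export
predict_patches <- function(model, features) {
  stopifnot(inherits(model, "hma_filter_model"))
  if (nrow(features) == 0L) return(logical(0))
  x <- sweep(sweep(as.matrix(features[model$features]), 2, model$center),
             2, model$scale, "/")
  predict(model$svm, as.data.frame(x)) == "1"
}

#' Remove predicted non-cell patches
#'
#' Surviving labels keep their exact pixel sets and are renumbered to
#' `1..n` without gaps; no pixel is ever added.
#'
#' @param labels Integer label matrix of candidate patches.
#' @param features Feature table from [compute_features()] (one row per
#'   label).
#' @param model An `hma_filter_model`.
#' @return Filtered integer label matrix.
#' @export
filter_patches <- function(labels, features, model) {
  n <- max(labels, 0L)
  if (nrow(features) != n)
    stop("feature table must have one row per label", call. = FALSE)
  if (n == 0L) return(labels)
  keep <- features$label[predict_patches(model, features)]
  out <- labels
  out[!(labels %in% keep)] <- 0L
  renumber_labels(out)
}

#' Persist / reload a patch-filter model
#'
#' @param model An `hma_filter_model`.
#' @param path File path.
#' @return `load_filter_model` returns the model; reloaded models reproduce
#'   identical predictions.
#' @export
save_filter_model <- function(model, path) {
  stopifnot(inherits(model, "hma_filter_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_filter_model
#' @export
load_filter_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hma_filter_model"))
    stop("not a patch-filter model: ", path, call. = FALSE)
  model
}

#' @exportS3Method base::print
print.hma_filter_model <- function(x, ...) {
  cat("patch-filter SVM:", x$meta$n_samples, "training patches,",
      x$meta$n_positive, "positive; held-out accuracy",
      round(x$meta$heldout_accuracy, 3), "\n")
  invisible(x)
}
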