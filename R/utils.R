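# Internal helpers shared across the pipeline. Images are plain numeric
# matrices on the [0,1] scale, masks are logical matrices, label maps are
# integer matrices with 0 = background. Coordinates are (row, col), 1-based.

#' @importFrom stats rnorm runif sd
NULL

as_numeric_matrix <- function(x, what = "image") {
  if (inherits(x, "hma_scene")) x <- x$image
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  x
}

check_intensity_image <- function(x, min_dim = 8L) {
  x <- as_numeric_matrix(x)
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim, " pixels", call. = FALSE)
  if (anyNA(x)) stop("image contains NA pixels", call. = FALSE)
  x
}

# disk structuring element of the given pixel radius
disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::dilate(mask * 1, disk_brush(radius)) > 0.5
}

binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::erode(mask * 1, disk_brush(radius)) > 0.5
}

binary_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  binary_erode(binary_dilate(mask, radius), radius)
}

#' 8- or 4-connected component labeling
#' @noRd
label_mask <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  label_components_cpp(mask > 0, as.integer(connectivity))
}

# remove connected components smaller than min_area pixels
area_open <- function(mask, min_area, connectivity = 8L) {
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_mask(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  mask | extract_holes(mask)
}

# shift a matrix by (dr, dc), replicating the nearest edge row/column
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# deterministic child seeds below 2^31 derived from one parent seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# renumber positive labels to 1..n in first-encounter (column-major) order
renumber_labels <- function(lab) {
  pos <- lab[lab > 0L]
  if (length(pos) == 0L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  ids <- unique(pos)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- map[pos]
  storage.mode(out) <- "integer"
  out
}
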