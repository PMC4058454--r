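# Reference images. Blurring fuses the minor intracellular structures into
# consistent patches so that local thresholding sees coherent sections
# rather than speckle. Two families are provided: iterated convolution with
# a truncated Gaussian kernel, and grayscale morphological smoothing by
# reconstruction (the flow used around marker-controlled watershed).

# normalized 1-D Gaussian kernel truncated at the given pixel radius
gaussian_kernel_1d <- function(sigma, radius) {
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  g / sum(g)
}

# sparse 1-D convolution operator with mirror (symmetric) boundary
conv_band_matrix <- function(n, kernel) {
  radius <- (length(kernel) - 1L) / 2L
  idx <- seq_len(n)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (o in -radius:radius) {
    j <- idx + o
    # mirror without repeating the edge sample: ..3 2 | 1 2 3.. -> reflect
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    ii <- c(ii, idx); jj <- c(jj, j)
    xx <- c(xx, rep(kernel[o + radius + 1L], n))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Iterated Gaussian blurring
#'
#' Convolves the image `n` times with a normalized Gaussian kernel truncated
#' at `radius` pixels (the blur level `n = 20`, `sigma = 1`, `radius = 5` is
#' the default reference configuration of the pipeline). The kernel is
#' separable, applied as row and column passes through sparse band
#' operators; borders are handled by mirror reflection so repeated passes do
#' not darken the frame. `n = 0` returns the input unchanged.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @param n Number of convolution passes (nonnegative).
#' @param radius Truncation radius in pixels; must be at least
#'   `ceiling(2 * sigma)`.
#' @return Blurred numeric matrix, same shape.
#' @export
iterated_gaussian <- function(image, sigma = 1.0, n = 20L, radius = 5L) {
  image <- as_numeric_matrix(image)
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (radius < ceiling(2 * sigma))
    stop("radius must be at least ceiling(2*sigma)", call. = FALSE)
  if (n == 0) return(image)
  k <- gaussian_kernel_1d(sigma, radius)
  R <- conv_band_matrix(nrow(image), k)
  C <- conv_band_matrix(ncol(image), k)
  out <- image
  for (i in seq_len(n)) out <- as.matrix(R %*% out %*% Matrix::t(C))
  dimnames(out) <- NULL
  out
}

#' Grayscale morphological smoothing by reconstruction
#'
#' Opening-by-reconstruction followed by closing-by-reconstruction with disk
#' structuring elements. Reconstruction-based smoothing flattens small
#' bright and dark details while preserving the contours of larger
#' structures, which is the standard preparation for marker-controlled
#' watershed. The output range never exceeds the input range.
#'
#' @param image Numeric matrix.
#' @param open_radius,close_radius Disk radii in pixels (at least 1).
#' @return Smoothed numeric matrix.
#' @export
graymorph_reference <- function(image, open_radius = 5L, close_radius = 5L) {
  image <- as_numeric_matrix(image)
  if (open_radius < 1 || close_radius < 1)
    stop("radii must be at least 1", call. = FALSE)
  er <- EBImage::erode(image, disk_brush(open_radius))
  opened <- reconstruct_dilation_cpp(as.matrix(er), image)
  di <- EBImage::dilate(opened, disk_brush(close_radius))
  # reconstruction by erosion via complementation
  closed <- 1 - reconstruct_dilation_cpp(1 - as.matrix(di), 1 - opened)
  dimnames(closed) <- NULL
  closed
}

#' Build the stack of reference images
#'
#' The default stack holds three layers: the original image, the 20-fold
#' Gaussian blur (`sigma = 1`, `radius = 5`), and the grayscale-morphology
#' smoothing of that blur. Strategy expressions bind their local Otsu
#' re-partitions to layers of this stack by name.
#'
#' @param image Numeric matrix in \[0,1\].
#' @param layers A named list describing the layers. Each element is a list
#'   with `type` one of `"original"`, `"gaussian"` (fields `n`, `sigma`,
#'   `radius`, optional `base`), or `"graymorph"` (fields `open_radius`,
#'   `close_radius`, optional `base` naming an earlier layer).
#' @return An object of class `hma_refstack`: named list of layers, each a
#'   list with `image` and `provenance`.
#' @export
build_reference_stack <- function(image, layers = default_reference_layers()) {
  image <- check_intensity_image(image)
  if (length(layers) == 0) stop("layer list must not be empty", call. = FALSE)
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must have unique names", call. = FALSE)
  out <- list()
  for (nm in names(layers)) {
    sp <- layers[[nm]]
    base <- if (!is.null(sp$base)) {
      if (is.null(out[[sp$base]]))
        stop("layer '", nm, "' refers to unknown base '", sp$base, "'", call. = FALSE)
      out[[sp$base]]$image
    } else image
    img <- switch(sp$type,
      original = base,
      gaussian = iterated_gaussian(base, sigma = sp$sigma, n = sp$n,
                                   radius = sp$radius),
      graymorph = graymorph_reference(base, open_radius = sp$open_radius,
                                      close_radius = sp$close_radius),
      stop("unknown reference layer type '", sp$type, "'", call. = FALSE))
    out[[nm]] <- list(image = img, provenance = sp)
  }
  structure(out, class = "hma_refstack")
}

#' @rdname build_reference_stack
#' @export
default_reference_layers <- function() {
  list(
    original  = list(type = "original"),
    gauss20   = list(type = "gaussian", n = 20L, sigma = 1.0, radius = 5L),
    graymorph = list(type = "graymorph", base = "gauss20",
                     open_radius = 5L, close_radius = 5L)
  )
}

#' @exportS3Method base::print
print.hma_refstack <- function(x, ...) {
  cat("reference stack:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
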