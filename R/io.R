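# Raster I/O. Grayscale intensities live on a canonical [0,1] scale
# regardless of the source bit depth; label maps round-trip bit-exactly
# through 16-bit single-channel TIFF; masks are written as {0,255} PNG.

#' Read a grayscale microscopy image
#'
#' Reads an 8- or 16-bit TIFF or PNG image and rescales intensities to the
#' canonical \[0,1\] scale by dividing by `2^bit_depth - 1`. RGB inputs are
#' converted to luminance (ITU-R BT.601: 0.299 R + 0.587 G + 0.114 B) before
#' rescaling. All pipeline thresholds are expressed on the \[0,1\] scale, so
#' 8- and 16-bit sources are interchangeable downstream.
#'
#' @param path Path to a TIFF or PNG file.
#' @return A numeric matrix in \[0,1\] with attribute `bit_depth_origin`
#'   (8 or 16). Images smaller than 8x8 pixels are rejected.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' img <- read_grayscale(f)
#' range(img)
#' @export
read_grayscale <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path, call. = FALSE))
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path), error = function(e)
      stop("not a readable PNG: ", path, call. = FALSE))
    # readPNG already rescales to [0,1]; recover the stored integers
    bits <- png_bit_depth(path)
    raw <- round(raw * (2^bits - 1))
  } else {
    stop("unsupported image format: .", ext, " (use TIFF or PNG)", call. = FALSE)
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 3L) {
      raw <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw <- raw[, , 1]
    }
  }
  if (!is.matrix(raw) || length(raw) == 0L)
    stop("not a 2-D raster: ", path, call. = FALSE)
  bits <- if (bits > 8) 16L else 8L
  img <- raw / (2^bits - 1)
  img <- check_intensity_image(img)
  attr(img, "bit_depth_origin") <- bits
  img
}

# PNG bit depth from the IHDR chunk (byte 25 of the file)
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("truncated PNG: ", path, call. = FALSE)
  as.integer(hdr[25L])
}

#' Write and read label maps as 16-bit TIFF
#'
#' Candidate-cell label maps (nonnegative integers, 0 = background) are
#' persisted as single-channel 16-bit TIFF so that a round trip through disk
#' returns identical values.
#'
#' @param labels Integer matrix of labels in 0..65535.
#' @param path Output path (`.tif`).
#' @return `write_label_map` returns `path` invisibly; `read_label_map`
#'   returns an integer matrix.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers", call. = FALSE)
  if (max(labels, 0) > 65535)
    stop("label map exceeds 16-bit capacity (max label > 65535)", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write a binary mask as a {0,255} PNG
#'
#' @param mask Logical matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- read_grayscale(path)
  m > 0.5
}
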