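#' Construct a calibrated micrograph
#'
#' A `micrograph` is the universal input of the package: a rectangular raster
#' of non-negative integer intensities together with the physical pixel size.
#' Pixels are stored as a base matrix indexed `[row, col]` with the origin at
#' the top-left; `x` is the column direction and `y` the row direction.
#'
#' @param pixels numeric matrix of intensities, all within the bit-depth range.
#' @param pixel_size_um physical edge length of one pixel in micrometres (> 0).
#' @param bit_depth 8 or 16.
#' @param source_id free-text provenance label.
#' @return An object of class `micrograph` with fields `pixels`, `bit_depth`,
#'   `pixel_size_um`, `source_id`.
#' @export
micrograph <- function(pixels, pixel_size_um, bit_depth = 8L,
                       source_id = "unknown") {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    sq_validation_error("pixels must be a non-empty matrix")
  if (!bit_depth %in% c(8L, 16L))
    sq_validation_error("bit_depth must be 8 or 16")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    sq_validation_error("pixel_size_um must be a single positive number")
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxv))
    sq_validation_error("intensities outside [0, %d] for bit depth %d",
                        maxv, bit_depth)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 pixel_size_um = as.numeric(pixel_size_um),
                 source_id = as.character(source_id)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %d-bit, %.4g um/px, source '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um,
              x$source_id))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  as.integer(hdr[25L])  # IHDR bit-depth byte
}

#' Load a micrograph from TIFF or PNG
#'
#' Reads a single-channel 8- or 16-bit raster and attaches the user-supplied
#' pixel calibration. SEM vendor metadata is deliberately ignored: scale
#' information in vendor TIFF tags is nonstandard, so the calibration must be
#' given explicitly. Multi-channel inputs are reduced to grayscale by the
#' unweighted channel mean, with a warning (SEM signal is physically
#' single-channel; color is incidental).
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param source_id provenance label; defaults to the file name.
#' @return A [micrograph].
#' @export
load_micrograph <- function(path, pixel_size_um, source_id = basename(path)) {
  if (!file.exists(path)) sq_input_error("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) sq_input_error(
                    "cannot decode TIFF '%s': %s", path, conditionMessage(e)))
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(x) > 255) 16L else 8L
    px <- x
  } else if (ext == "png") {
    x <- tryCatch(png::readPNG(path),
                  error = function(e) sq_input_error(
                    "cannot decode PNG '%s': %s", path, conditionMessage(e)))
    bits <- png_bit_depth(path)
    if (!bits %in% c(8L, 16L))
      sq_input_error("unsupported PNG bit depth %d in '%s'", bits, path)
    px <- round(x * (2^bits - 1))
  } else sq_input_error("unsupported image format '.%s' (use TIFF or PNG)", ext)
  if (length(dim(px)) == 3L) {
    warning("multi-channel image reduced to grayscale by channel mean",
            call. = FALSE)
    px <- apply(px, c(1L, 2L), mean)
  }
  if (!is.matrix(px)) px <- matrix(px, nrow = dim(px)[1L])
  micrograph(px, pixel_size_um, bit_depth = as.integer(bits),
             source_id = source_id)
}

#' Write a micrograph to TIFF or PNG
#'
#' Inverse of [load_micrograph()]: intensities are written exactly. 16-bit
#' images must be written as TIFF.
#'
#' @param m a [micrograph].
#' @param path output path ending in `.tif`, `.tiff`, or `.png`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  ext <- tolower(tools::file_ext(path))
  scaled <- m$pixels / (2^m$bit_depth - 1)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = m$bit_depth)
  } else if (ext == "png") {
    if (m$bit_depth != 8L)
      sq_validation_error("PNG output supports 8-bit only; use TIFF")
    png::writePNG(scaled, path)
  } else sq_input_error("unsupported output format '.%s'", ext)
  invisible(path)
}

#' Load a binary mask image
#'
#' Any nonzero pixel is foreground. Returns a [binary_mask] carrying the
#' calibration.
#'
#' @inheritParams load_micrograph
#' @return A [binary_mask].
#' @export
load_mask <- function(path, pixel_size_um, source_id = basename(path)) {
  m <- load_micrograph(path, pixel_size_um, source_id)
  binary_mask(m$pixels > 0, pixel_size_um,
              method_record = list(method = "external_mask", file = source_id))
}
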