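#' Construct a binary mask
#'
#' @param pixels logical matrix (TRUE = foreground).
#' @param pixel_size_um pixel edge length in micrometres.
#' @param method_record list describing how the mask was produced (threshold
#'   method and parameters); always populated, for reproducibility.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um, method_record = list(method = "manual")) {
  if (!is.matrix(pixels) || !is.logical(pixels) || length(pixels) == 0L)
    sq_validation_error("pixels must be a non-empty logical matrix")
  if (pixel_size_um <= 0) sq_validation_error("pixel_size_um must be > 0")
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
                 method_record = method_record),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground (%.1f%%), method '%s'\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels), x$method_record$method))
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' Threshold a micrograph into a binary mask
#'
#' Global thresholding, the front end of the silhouette pipeline. Otsu's
#' method (parameter-free, reproducible) is the default; a manual threshold is
#' available for low-contrast inputs. Foreground is the bright side
#' (`intensity > threshold`) unless `invert = TRUE`.
#'
#' @param m a [micrograph].
#' @param method `"otsu"` or `"manual"`.
#' @param manual_threshold intensity cutoff (required when `method = "manual"`),
#'   within the bit-depth range.
#' @param invert take the dark side as foreground.
#' @return A [binary_mask] with `method_record` filled.
#' @export
binarize <- function(m, method = c("otsu", "manual"), manual_threshold = NULL,
                     invert = FALSE) {
  stopifnot(inherits(m, "micrograph"))
  method <- match.arg(method)
  maxv <- 2^m$bit_depth - 1
  if (method == "otsu") {
    if (var(as.vector(m$pixels)) == 0)
      sq_degenerate_error(paste("image has zero intensity variance; Otsu",
                                "threshold is undefined - use method='manual'"))
    thr <- EBImage::otsu(m$pixels / maxv, range = c(0, 1),
                         levels = 2^m$bit_depth) * maxv
  } else {
    if (is.null(manual_threshold) || manual_threshold < 0 || manual_threshold > maxv)
      sq_validation_error("manual_threshold must lie in [0, %d]", maxv)
    thr <- manual_threshold
  }
  fg <- if (invert) m$pixels < thr else m$pixels > thr
  binary_mask(fg, m$pixel_size_um,
              method_record = list(method = method, threshold = as.numeric(thr),
                                   invert = invert, source_id = m$source_id))
}

#' Clean a binary mask
#'
#' Removes connected components smaller than `min_object_px` (speck
#' suppression) and optionally fills interior holes. An empty mask is allowed
#' and returned unchanged.
#'
#' @param mask a [binary_mask].
#' @param min_object_px minimum component size in pixels (>= 0).
#' @param fill_holes fill interior background holes.
#' @param connectivity 4 or 8, used for the component-size filter.
#' @return A cleaned [binary_mask]; `method_record` is extended.
#' @export
clean_mask <- function(mask, min_object_px = 0L, fill_holes = FALSE,
                       connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (min_object_px < 0) sq_validation_error("min_object_px must be >= 0")
  px <- mask$pixels
  if (any(px) && min_object_px > 0L) {
    lab <- label_matrix(px, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    px <- matrix(lab %in% keep, nrow(px), ncol(px))
  }
  if (fill_holes && any(px))
    px <- EBImage::fillHull(px * 1L) > 0
  rec <- mask$method_record
  rec$min_object_px <- as.integer(min_object_px)
  rec$fill_holes <- fill_holes
  binary_mask(px, mask$pixel_size_um, rec)
}

# Connected-component labels as an integer matrix. EBImage::bwlabel is
# 4-connected; for 8-connectivity, diagonally adjacent 4-components are merged
# by a union pass over the (small) label adjacency graph.
label_matrix <- function(px, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) sq_validation_error("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(px * 1L)
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),   # SE
      cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc])))   # SW
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) {
      g <- igraph::graph_from_edgelist(unique(pairs) , directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
      comp <- igraph::components(g)$membership
      remap <- c(0L, as.integer(comp[seq_len(nlab)]))
      lab <- matrix(remap[lab + 1L], nr, nc)
    }
  }
  # compact label ids to 1..k in first-appearance order
  ids <- unique(as.vector(lab)); ids <- ids[ids > 0L]
  remap <- integer(max(lab) + 1L); remap[ids + 1L] <- seq_along(ids)
  matrix(remap[lab + 1L], nrow(px), ncol(px))
}

#' Extract labeled cell instances from a mask
#'
#' Each foreground connected component becomes one `cell_instance` holding its
#' pixel coordinates, a cropped sub-mask, and its ordered outer boundary
#' contour. Components touching the raster border are flagged (their
#' dimensions are censored by the field of view) and can be excluded.
#'
#' @param mask a [binary_mask].
#' @param connectivity 4 or 8 (default 8: thin diagonal structures such as
#'   neurites stay connected).
#' @param exclude_border drop border-touching components.
#' @return List of `cell_instance` objects, each with fields `cell_id`,
#'   `pixels` (n x 2 matrix of row/col), `mask` (cropped logical matrix),
#'   `offset` (row/col offset such that global = local + offset), `outline`
#'   (ordered closed contour, n x 2 row/col), `touches_border`,
#'   `pixel_size_um`.
#' @export
label_instances <- function(mask, connectivity = 8L, exclude_border = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  if (!any(px)) return(list())
  lab <- label_matrix(px, connectivity)
  nlab <- max(lab)
  contours <- EBImage::ocontour(lab)
  nr <- nrow(px); nc <- ncol(px)
  out <- vector("list", nlab)
  coords_all <- which(lab > 0L, arr.ind = TRUE)
  lab_vals <- lab[lab > 0L]
  for (k in seq_len(nlab)) {
    coords <- coords_all[lab_vals == k, , drop = FALSE]
    touches <- any(coords[, 1L] == 1L | coords[, 1L] == nr |
                   coords[, 2L] == 1L | coords[, 2L] == nc)
    r0 <- min(coords[, 1L]) - 1L; c0 <- min(coords[, 2L]) - 1L
    sub <- matrix(FALSE, max(coords[, 1L]) - r0, max(coords[, 2L]) - c0)
    sub[cbind(coords[, 1L] - r0, coords[, 2L] - c0)] <- TRUE
    ctr <- contours[[k]] + 1L  # ocontour is 0-based
    colnames(ctr) <- c("row", "col")
    out[[k]] <- structure(list(
      cell_id = k, pixels = unname(coords), mask = sub,
      offset = c(row = r0, col = c0), outline = ctr,
      touches_border = touches, pixel_size_um = mask$pixel_size_um),
      class = "cell_instance")
  }
  if (exclude_border)
    out <- Filter(function(ci) !ci$touches_border, out)
  out
}

#' @export
print.cell_instance <- function(x, ...) {
  cat(sprintf("<cell_instance> id %d, %d px, border: %s\n", x$cell_id,
              nrow(x$pixels), x$touches_border))
  invisible(x)
}

# padded cropped mask (1-px FALSE ring) for distance/skeleton operations
padded_mask <- function(cell) {
  m <- cell$mask
  p <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  p
}
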