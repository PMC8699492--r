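# Rod (bacterial) morphometry: per-cell length, width, aspect ratio,
# projected area, spherocylinder model volume/surface, and S/V.

#' Spherocylinder volume of a rod-shaped cell
#'
#' The standard geometric model of a rod-shaped bacterium is a cylinder of
#' width W capped by two hemispheres; its volume is
#' \deqn{V = \frac{\pi W^2}{4}\left(L - \frac{W}{3}\right)}
#' where L is the total (cap-to-cap) length. For L = W the model degenerates
#' to a sphere and V = pi W^3 / 6 exactly.
#'
#' @param length_L total cell length in micrometres.
#' @param width_W cell width (diameter) in micrometres; must satisfy
#'   `0 < width_W <= length_L` (the model assumes a rod).
#' @return Volume in cubic micrometres.
#' @export
rod_volume <- function(length_L, width_W) {
  check_rod_dims(length_L, width_W)
  (pi * width_W^2 / 4) * (length_L - width_W / 3)
}

#' Spherocylinder surface area of a rod-shaped cell
#'
#' Cylinder side plus two hemispherical caps:
#' \eqn{S = \pi W (L - W) + \pi W^2 = \pi W L}. This is the 3-D model
#' surface; it is distinct from the 2-D projected area an SEM image measures.
#'
#' @inheritParams rod_volume
#' @return Surface area in square micrometres.
#' @export
rod_surface <- function(length_L, width_W) {
  check_rod_dims(length_L, width_W)
  pi * width_W * length_L
}

check_rod_dims <- function(length_L, width_W) {
  if (any(!is.finite(length_L)) || any(!is.finite(width_W)) ||
      any(length_L <= 0) || any(width_W <= 0))
    sq_validation_error("length and width must be positive")
  if (any(width_W > length_L))
    sq_validation_error("width exceeds length: spherocylinder model requires W <= L")
  invisible(TRUE)
}

#' Aspect ratio of a rod
#'
#' Width divided by length: close to 1 for circular silhouettes, about 0.25
#' for E. coli rods. Values marginally above 1 caused by measurement noise are
#' clipped to 1 with a warning.
#'
#' @inheritParams rod_volume
#' @return W/L in (0, 1].
#' @export
aspect_ratio <- function(width_W, length_L) {
  if (any(!is.finite(width_W)) || any(!is.finite(length_L)) ||
      any(width_W <= 0) || any(length_L <= 0))
    sq_validation_error("width and length must be positive")
  r <- width_W / length_L
  if (any(r > 1)) {
    if (any(r > 1.05))
      sq_validation_error("width substantially exceeds length (ratio %.3f)", max(r))
    warning("aspect ratio marginally > 1 clipped to 1 (measurement noise)",
            call. = FALSE)
    r <- pmin(r, 1)
  }
  r
}

#' Measure length, width and projected area of one rod-shaped cell
#'
#' An automated surrogate for manual tracing, orientation-independent and
#' tolerant of curved rods: the silhouette is skeletonized, length is the
#' geodesic length of the longest medial-axis path extended at both ends by
#' the local medial radius, and width is twice the mean distance-transform
#' radius sampled along the medial axis (matching the constant-width
#' spherocylinder model). Projected area is the pixel count times the pixel
#' area.
#'
#' @param cell a `cell_instance` from [label_instances()].
#' @param pixel_size_um pixel edge length in micrometres; defaults to the
#'   calibration carried by the instance.
#' @param min_pixels minimum instance size; below this the width estimate is
#'   dominated by quantization and the cell is rejected.
#' @param feret also report max/min Feret (caliper) diameters as a
#'   cross-check on the medial-axis estimates.
#' @return Named list: `length_um`, `width_um`, `projected_area_um2` (plus
#'   `feret_length_um`, `feret_width_um` when requested).
#' @export
measure_rod <- function(cell, pixel_size_um = cell$pixel_size_um,
                        min_pixels = 25L, feret = FALSE) {
  stopifnot(inherits(cell, "cell_instance"))
  npx <- nrow(cell$pixels)
  if (npx < min_pixels)
    sq_measurement_error("cell %d has %d px (< %d): too small to measure",
                         cell$cell_id, npx, min_pixels)
  p <- padded_mask(cell)
  dm <- distance_map(p)
  skel <- skeletonize(p)
  if (!any(skel))
    sq_measurement_error("cell %d: skeletonization produced no medial axis",
                         cell$cell_id)
  radii <- dm[skel] - 0.5
  width_px <- 2 * mean(radii)
  sg <- skeleton_graph(skel)
  dia <- skeleton_diameter(sg)
  r_from <- dm[dia$from[1L], dia$from[2L]] - 0.5
  r_to <- dm[dia$to[1L], dia$to[2L]] - 0.5
  length_px <- dia$length_px + r_from + r_to
  if (length_px < width_px) {  # near-circular: caliper symmetry
    length_px <- max(length_px, width_px)
  }
  out <- list(length_um = length_px * pixel_size_um,
              width_um = width_px * pixel_size_um,
              projected_area_um2 = npx * pixel_size_um^2)
  if (feret) {
    f <- feret_diameters(cell$pixels)
    out$feret_length_um <- f[["max"]] * pixel_size_um
    out$feret_width_um <- f[["min"]] * pixel_size_um
  }
  out
}

# Max Feret = largest pairwise distance between hull pixels (+1 px to account
# for pixel extent); min Feret = smallest hull width over edge directions.
feret_diameters <- function(coords) {
  h <- grDevices::chull(coords)
  pts <- coords[h, , drop = FALSE]
  d <- as.matrix(stats::dist(pts))
  fmax <- max(d) + 1
  n <- nrow(pts)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nvec <- c(-e[2L], e[1L]) / len
    proj <- (pts[, 1L] - pts[i, 1L]) * nvec[1L] +
            (pts[, 2L] - pts[i, 2L]) * nvec[2L]
    diff(range(proj))
  }, numeric(1L))
  c(max = fmax, min = min(widths) + 1)
}

#' Full rod morphometry of a cell population
#'
#' Applies [measure_rod()] to every instance, derives aspect ratio,
#' spherocylinder volume and surface, and S/V, and reports per-cell values
#' plus population summaries (mean, sd, n per descriptor, as rod dimensions
#' are conventionally reported). Cells failing the size precondition or the
#' rod model (W > L beyond noise) are listed with a reason and excluded from
#' summaries.
#'
#' @param cells list of `cell_instance` objects.
#' @param pixel_size_um calibration in micrometres per pixel.
#' @param min_pixels passed to [measure_rod()].
#' @param source_id provenance label for the result table.
#' @return List with `per_cell` (data frame), `summary` (data frame of mean,
#'   sd, n per descriptor), `table` (long [result_table]), and `skipped`
#'   (data frame of cell_id + reason).
#' @export
measure_population <- function(cells, pixel_size_um, min_pixels = 25L,
                               source_id = "unknown") {
  if (length(cells) == 0L)
    sq_degenerate_error("no cell instances supplied")
  rows <- list(); skipped <- list()
  for (cell in cells) {
    res <- tryCatch({
      m <- measure_rod(cell, pixel_size_um, min_pixels = min_pixels)
      L <- m$length_um; W <- min(m$width_um, m$length_um)
      ar <- suppressWarnings(aspect_ratio(m$width_um, m$length_um))
      V <- rod_volume(L, W); S <- rod_surface(L, W)
      data.frame(cell_id = cell$cell_id, length_um = L, width_um = m$width_um,
                 aspect_ratio = ar, projected_area_um2 = m$projected_area_um2,
                 volume_um3 = V, surface_um2 = S, sv_ratio_per_um = S / V)
    }, semquant_error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(cell_id = cell$cell_id, reason = conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L)
    sq_degenerate_error("no measurable cells (all %d skipped)", length(skipped))
  per_cell <- do.call(rbind, rows)
  desc <- setdiff(names(per_cell), "cell_id")
  summary <- data.frame(
    descriptor = desc,
    mean = vapply(desc, function(d) mean(per_cell[[d]]), numeric(1L)),
    sd = vapply(desc, function(d) sd(per_cell[[d]]), numeric(1L)),
    n = nrow(per_cell), row.names = NULL)
  summary$sd[is.na(summary$sd)] <- 0
  list(per_cell = per_cell, summary = summary,
       table = as_result_table(per_cell, source_id),
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(cell_id = integer(), reason = character()))
}
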