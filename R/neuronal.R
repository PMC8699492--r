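# Neuronal morphometry: soma identification, neurite tracing on the medial
# axis, length/radial-distance/straightness, angular alignment classes, and
# the area/perimeter/circularity shape descriptors.
#
# Angle convention: angles are measured in degrees from the +x axis (columns)
# counterclockwise in the conventional plot orientation, i.e. with y pointing
# up the image (decreasing row index). Alignment angles are folded into
# [0, 90] degrees, so the convention only fixes the meaning of the reference
# axis.

#' Identify the soma of a neuron silhouette
#'
#' The soma (cell body) is operationalized as the maximal inscribed disc of
#' the silhouette: its center is the argmax of the Euclidean distance
#' transform and its radius the maximum distance value. Ties between equal
#' maxima are broken deterministically (lowest row, then lowest column) with
#' a warning.
#'
#' @param cell a `cell_instance`.
#' @return List: `center` (global row/col), `diameter_um`, `radius_px`,
#'   `center_local` (row/col in the padded crop frame used by
#'   [extract_neurites()]).
#' @export
identify_soma <- function(cell) {
  stopifnot(inherits(cell, "cell_instance"))
  p <- padded_mask(cell)
  dm <- distance_map(p)
  mx <- max(dm)
  hits <- which(dm == mx, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    warning("multiple inscribed-disc maxima; deterministic tie-break applied",
            call. = FALSE)
  }
  ctr <- hits[1L, ]
  radius_px <- mx - 0.5
  list(center = c(row = ctr[[1L]] - 1L + cell$offset[["row"]],
                  col = ctr[[2L]] - 1L + cell$offset[["col"]]),
       diameter_um = 2 * radius_px * cell$pixel_size_um,
       radius_px = radius_px,
       center_local = c(row = ctr[[1L]], col = ctr[[2L]]))
}

#' Trace neurites of a neuron silhouette
#'
#' The silhouette is thinned to its medial axis; skeleton pixels inside the
#' soma disc are removed; each remaining connected skeleton subtree anchored
#' at the soma boundary becomes one neurite, whose path is the longest
#' geodesic branch from its anchor to a skeleton endpoint. The tip is
#' extended by the local medial radius (the skeleton retreats from the
#' silhouette tip by about the process half-width) and the base is projected
#' onto the soma boundary, so lengths refer to the boundary-to-tip extent.
#' Traces shorter than `min_neurite_um` are discarded (skeleton spur
#' suppression).
#'
#' @param cell a `cell_instance`.
#' @param soma result of [identify_soma()]; computed if missing.
#' @param min_neurite_um minimum neurite length in micrometres; default 5
#'   pixels at the instance calibration.
#' @return List of `neurite_trace` objects with fields `neurite_id`, `path`
#'   (n x 2 skeleton coordinates, padded-crop frame), `base`, `tip` (float
#'   row/col, boundary-projected base and radius-extended tip), `length_um`.
#' @export
extract_neurites <- function(cell, soma = identify_soma(cell),
                             min_neurite_um = 5 * cell$pixel_size_um) {
  stopifnot(inherits(cell, "cell_instance"))
  s <- cell$pixel_size_um
  p <- padded_mask(cell)
  dm <- distance_map(p)
  skel <- skeletonize(p)
  ctr <- soma$center_local
  rad <- soma$radius_px
  # remove skeleton inside the soma disc
  sc <- which(skel, arr.ind = TRUE)
  if (nrow(sc) == 0L) return(list())
  d2c <- sqrt((sc[, 1L] - ctr[["row"]])^2 + (sc[, 2L] - ctr[["col"]])^2)
  keep <- d2c > rad
  pruned <- matrix(FALSE, nrow(p), ncol(p))
  pruned[sc[keep, , drop = FALSE]] <- TRUE
  if (!any(pruned)) return(list())
  sg <- skeleton_graph(pruned)
  comp <- igraph::components(sg$graph)$membership
  dc <- sqrt((sg$coords[, 1L] - ctr[["row"]])^2 +
             (sg$coords[, 2L] - ctr[["col"]])^2)
  traces <- list()
  for (k in sort(unique(comp))) {
    idx <- which(comp == k)
    d_near <- min(dc[idx])
    if (d_near > rad + 2)  # not anchored at the soma boundary: orphan spur
      next
    anchor_cands <- idx[dc[idx] == d_near]
    if (length(anchor_cands) > 1L) {
      oc <- order(sg$coords[anchor_cands, 1L], sg$coords[anchor_cands, 2L])
      anchor_cands <- anchor_cands[oc]
    }
    anchor <- anchor_cands[1L]
    lp <- skeleton_longest_from(sg, anchor)
    path <- lp$path
    np <- nrow(path)
    tip_i <- path[np, ]
    tip_radius <- dm[tip_i[1L], tip_i[2L]] - 0.5
    # extend tip along the terminal path direction
    m <- max(1L, np - 5L)
    dirv <- path[np, ] - path[m, ]
    nv <- sqrt(sum(dirv^2))
    tip <- if (nv > 0) tip_i + dirv / nv * tip_radius else tip_i
    # project base onto the soma boundary along center -> anchor
    av <- sg$coords[anchor, ] - c(ctr[["row"]], ctr[["col"]])
    an <- sqrt(sum(av^2))
    base <- c(ctr[["row"]], ctr[["col"]]) + av / an * rad
    length_px <- lp$length_px + tip_radius + max(0, an - rad)
    length_um <- length_px * s
    if (length_um < min_neurite_um) next
    traces[[length(traces) + 1L]] <- structure(list(
      neurite_id = NA_integer_, path = path,
      base = c(row = unname(base[1L]), col = unname(base[2L])),
      tip = c(row = tip[[1L]], col = tip[[2L]]),
      length_um = length_um, pixel_size_um = s), class = "neurite_trace")
  }
  if (length(traces)) {
    ord <- order(vapply(traces, function(t) t$base[["row"]], numeric(1L)),
                 vapply(traces, function(t) t$base[["col"]], numeric(1L)))
    traces <- traces[ord]
    for (i in seq_along(traces)) traces[[i]]$neurite_id <- i
  }
  traces
}

#' Neurite count and length statistics
#'
#' Count is the number of neurites exiting the cell body; average length is
#' the sum of all neurite lengths divided by the count; maximum length is the
#' longest neurite. With no neurites the count is 0 and the lengths are
#' undefined (`NA`), not zero.
#'
#' @param traces list of `neurite_trace` objects.
#' @return Named list: `neurite_count`, `avg_neurite_length_um`,
#'   `max_neurite_length_um`.
#' @export
neurite_stats <- function(traces) {
  n <- length(traces)
  if (n == 0L)
    return(list(neurite_count = 0L, avg_neurite_length_um = NA_real_,
                max_neurite_length_um = NA_real_))
  len <- vapply(traces, function(t) t$length_um, numeric(1L))
  list(neurite_count = n, avg_neurite_length_um = mean(len),
       max_neurite_length_um = max(len))
}

#' Radial distance and straightness of a neurite
#'
#' Radial distance is the straight-line (Euclidean) distance from the neurite
#' base to its tip; straightness is the difference between the traced neurite
#' length and the radial distance, which is zero for a perfectly straight
#' neurite and grows with tortuosity. By the triangle inequality the length
#' can never be below the radial distance; sub-pixel excesses from endpoint
#' extension are clamped to zero.
#'
#' @param trace a `neurite_trace`.
#' @return Named list: `radial_distance_um`, `straightness_um`, and the
#'   dimensionless `tortuosity` (length / radial distance; an extension to
#'   the classical difference form).
#' @export
radial_and_straightness <- function(trace) {
  stopifnot(inherits(trace, "neurite_trace"))
  if (nrow(trace$path) < 1L)
    sq_validation_error("trace has no points")
  chord <- trace$tip - trace$base
  radial <- sqrt(sum(chord^2)) * trace$pixel_size_um
  if (radial > trace$length_um) {
    if (radial - trace$length_um > 1.5 * trace$pixel_size_um)
      sq_measurement_error("radial distance exceeds traced length beyond tolerance")
    radial <- trace$length_um
  }
  list(radial_distance_um = radial,
       straightness_um = trace$length_um - radial,
       tortuosity = if (radial > 0) trace$length_um / radial else NA_real_)
}

#' Chord angle of a neurite relative to a reference axis
#'
#' A straight line is drawn from the neurite base to its tip and the acute
#' angle between that chord and the reference axis is reported, folded into
#' [0, 90] degrees. The reference axis defaults to 0 (the image x-axis); for
#' unpatterned substrates a random axis may be drawn by the caller.
#'
#' @param trace a `neurite_trace` (or any list with `base` and `tip`
#'   row/col fields).
#' @param reference_axis_deg reference axis in degrees.
#' @return Chord angle in [0, 90] degrees.
#' @export
alignment_angle <- function(trace, reference_axis_deg = 0) {
  chord <- trace$tip - trace$base
  dx <- chord[["col"]]; dy <- -chord[["row"]]  # y up
  if (dx == 0 && dy == 0)
    sq_degenerate_error("zero-length chord: alignment angle undefined")
  theta <- atan2(dy, dx) * 180 / pi
  a <- abs(theta - reference_axis_deg) %% 180
  if (a > 90) a <- 180 - a
  a
}

#' Classify neurite alignment
#'
#' Neurites at less than 15 degrees to the reference axis are scored
#' parallel; at more than 75 degrees, perpendicular; the unnamed band between
#' is reported as intermediate. The inequalities are strict, so 15 and 75
#' exactly fall in the intermediate class.
#'
#' @param chord_angle_deg angle in [0, 90] degrees.
#' @return One of `"parallel"`, `"intermediate"`, `"perpendicular"`.
#' @export
classify_alignment <- function(chord_angle_deg) {
  if (any(!is.finite(chord_angle_deg)) || any(chord_angle_deg < 0) ||
      any(chord_angle_deg > 90))
    sq_validation_error("chord angle must lie in [0, 90] degrees")
  ifelse(chord_angle_deg < 15, "parallel",
         ifelse(chord_angle_deg > 75, "perpendicular", "intermediate"))
}

#' Area, perimeter and circularity of a cell silhouette
#'
#' Area A is the pixel count times the pixel area. Perimeter P is estimated
#' from the ordered boundary contour; circularity is
#' \deqn{C = \frac{4\pi A}{P^2},}
#' equal to 1 for a disc and decreasing with boundary irregularity.
#'
#' Perimeter estimators: `"calibrated"` (default) uses chain-code weights
#' calibrated for digitized smooth boundaries (0.980 per axial step, 1.406
#' per diagonal step, -0.091 per direction change, after
#' Vossepoel & Smeulders), which makes a large rasterized disc measure
#' C = 1.00 within about 0.01 as the continuous formula requires;
#' `"chain"` is the naive chain length (1 / sqrt(2) weights), which
#' overestimates smooth perimeters by about 5%; `"pixel_count"` is the raw
#' number of boundary pixels (the literal pixel-counting reading, biased low
#' on diagonals).
#'
#' @param cell a `cell_instance`.
#' @param pixel_size_um calibration; defaults to the instance's.
#' @param perimeter_method one of `"calibrated"`, `"chain"`, `"pixel_count"`.
#' @return Named list: `area_um2`, `perimeter_um`, `circularity`.
#' @export
area_perimeter_circularity <- function(cell,
                                       pixel_size_um = cell$pixel_size_um,
                                       perimeter_method = c("calibrated",
                                                            "chain",
                                                            "pixel_count")) {
  stopifnot(inherits(cell, "cell_instance"))
  perimeter_method <- match.arg(perimeter_method)
  A <- nrow(cell$pixels) * pixel_size_um^2
  P <- contour_perimeter(cell$outline, perimeter_method) * pixel_size_um
  list(area_um2 = A, perimeter_um = P, circularity = circularity(A, P))
}

#' Circularity from area and perimeter
#'
#' The continuous-geometry form \eqn{C = 4\pi A / P^2}: exactly 1 for an
#' ideal disc (A = pi r^2, P = 2 pi r), below 1 for any other shape.
#'
#' @param area area (any consistent unit).
#' @param perimeter perimeter (same length unit).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    sq_validation_error("area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

# Perimeter of an ordered closed contour (n x 2 row/col pixel chain).
contour_perimeter <- function(outline, method = "calibrated") {
  n <- nrow(outline)
  if (n == 1L) return(if (method == "pixel_count") 1 else 4)  # lone pixel
  d <- rbind(outline[-1L, , drop = FALSE] - outline[-n, , drop = FALSE],
             outline[1L, ] - outline[n, ])
  keep <- !(d[, 1L] == 0 & d[, 2L] == 0)
  d <- d[keep, , drop = FALSE]
  diag_step <- abs(d[, 1L]) + abs(d[, 2L]) == 2L
  switch(method,
    pixel_count = nrow(unique(outline)),
    chain = sum(ifelse(diag_step, sqrt(2), 1)),
    calibrated = {
      ang <- atan2(d[, 2L], d[, 1L])
      n_corner <- sum(ang != c(ang[-1L], ang[1L]))
      0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * n_corner
    })
}

#' Measure one neuron silhouette
#'
#' Orchestrates [identify_soma()], [extract_neurites()], [neurite_stats()],
#' alignment classification and [area_perimeter_circularity()] for a single
#' instance, and flags the cell as differentiated when at least one neurite
#' is as long as the soma diameter.
#'
#' @inheritParams extract_neurites
#' @inheritParams area_perimeter_circularity
#' @param reference_axis_deg alignment reference axis in degrees.
#' @return List: `morph` (one-row data frame of all per-cell descriptors),
#'   `traces` (list of `neurite_trace`, each augmented with
#'   `radial_distance_um`, `straightness_um`, `tortuosity`,
#'   `chord_angle_deg`, `alignment_class`).
#' @export
measure_neuron <- function(cell, reference_axis_deg = 0,
                           min_neurite_um = 5 * cell$pixel_size_um,
                           perimeter_method = "calibrated") {
  soma <- identify_soma(cell)
  traces <- extract_neurites(cell, soma, min_neurite_um = min_neurite_um)
  for (i in seq_along(traces)) {
    rs <- radial_and_straightness(traces[[i]])
    traces[[i]]$radial_distance_um <- rs$radial_distance_um
    traces[[i]]$straightness_um <- rs$straightness_um
    traces[[i]]$tortuosity <- rs$tortuosity
    a <- alignment_angle(traces[[i]], reference_axis_deg)
    traces[[i]]$chord_angle_deg <- a
    traces[[i]]$alignment_class <- classify_alignment(a)
  }
  ns <- neurite_stats(traces)
  apc <- area_perimeter_circularity(cell, perimeter_method = perimeter_method)
  classes <- vapply(traces, function(t) t$alignment_class, character(1L))
  differentiated <- ns$neurite_count > 0L &&
    ns$max_neurite_length_um >= soma$diameter_um
  morph <- data.frame(
    cell_id = cell$cell_id,
    soma_diameter_um = soma$diameter_um,
    neurite_count = ns$neurite_count,
    avg_neurite_length_um = ns$avg_neurite_length_um,
    max_neurite_length_um = ns$max_neurite_length_um,
    area_um2 = apc$area_um2, perimeter_um = apc$perimeter_um,
    circularity = apc$circularity,
    n_parallel = sum(classes == "parallel"),
    n_intermediate = sum(classes == "intermediate"),
    n_perpendicular = sum(classes == "perpendicular"),
    is_differentiated = as.integer(differentiated))
  list(morph = morph, traces = traces, soma = soma)
}

#' Measure a field of neurons
#'
#' Applies [measure_neuron()] to every instance and binds the per-cell rows.
#'
#' @param cells list of `cell_instance` objects.
#' @inheritParams measure_neuron
#' @param source_id provenance label for the result table.
#' @return List: `per_cell` data frame, `traces` (list per cell), `table`
#'   (long [result_table]).
#' @export
measure_neuron_population <- function(cells, reference_axis_deg = 0,
                                      min_neurite_um = NULL,
                                      perimeter_method = "calibrated",
                                      source_id = "unknown") {
  if (length(cells) == 0L) sq_degenerate_error("no cell instances supplied")
  res <- lapply(cells, function(cell) {
    mnu <- if (is.null(min_neurite_um)) 5 * cell$pixel_size_um else min_neurite_um
    measure_neuron(cell, reference_axis_deg, mnu, perimeter_method)
  })
  per_cell <- do.call(rbind, lapply(res, `[[`, "morph"))
  tab_df <- per_cell
  tab_df$avg_neurite_length_um[is.na(tab_df$avg_neurite_length_um)] <- NA_real_
  list(per_cell = per_cell, traces = lapply(res, `[[`, "traces"),
       table = as_result_table(per_cell, source_id))
}

#' Count differentiated cells
#'
#' A cell is scored differentiated when it bears at least one neurite whose
#' length equals or exceeds its soma diameter. Cells without neurites are not
#' counted.
#'
#' @param cells a data frame with columns `max_neurite_length_um`,
#'   `soma_diameter_um`, `neurite_count` (e.g. the `per_cell` component of
#'   [measure_neuron_population()]), or a list of [measure_neuron()] results.
#' @return Integer count.
#' @export
count_differentiated <- function(cells) {
  if (is.data.frame(cells)) df <- cells
  else df <- do.call(rbind, lapply(cells, function(x)
    if (is.list(x) && !is.null(x$morph)) x$morph else as.data.frame(x)))
  ok <- df$neurite_count > 0L &
    !is.na(df$max_neurite_length_um) &
    df$max_neurite_length_um >= df$soma_diameter_um
  sum(ok)
}
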