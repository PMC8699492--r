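# Seeded synthetic-image generators with exact ground truth. These emulate
# the geometry and statistics of SEM micrographs of rod-shaped bacteria and
# neuron-like cells (not their rendering: no charging artifacts or
# topographic shading), plus analytic fractal and texture test patterns, so
# every measurement module can be validated end to end without external data.

#' Generate a population of rod-shaped bacterial silhouettes
#'
#' Rods are spherocylinders (all pixels within W/2 of an axis segment) with
#' lengths drawn uniformly from `length_range_um`, width W = aspect x L, and
#' uniformly random orientation. Rods are placed by rejection sampling so
#' that silhouettes never overlap or touch the border. The default
#' parameters are the E. coli preset: L ~ U(2, 4) um, aspect 0.25, at
#' 0.02 um/px. Foreground intensity 180 on background 20 (8-bit), with
#' optional additive Gaussian noise, clipped to range.
#'
#' @param n number of rods.
#' @param length_range_um uniform length range in micrometres.
#' @param aspect width-to-length ratio W/L in (0, 1].
#' @param orientation_range_deg uniform orientation range in degrees.
#' @param pixel_size_um calibration.
#' @param image_px image edge length in pixels; `NULL` picks a size that
#'   comfortably fits `n` rods.
#' @param noise_sd additive Gaussian noise sd in intensity units.
#' @param seed RNG seed (bit-identical regeneration from the same seed).
#' @param fg,bg foreground/background intensities.
#' @param gap_um minimum clearance between rod silhouettes.
#' @param max_tries placement attempts before a capacity error.
#' @return List: `micrograph`, `mask` (noise-free [binary_mask]), `truth`
#'   (data frame: object_id, length_um, width_um, aspect, orientation_deg,
#'   center row/col, pixel count) plus attributes `seed`, `pixel_size_um`,
#'   `n_foreground_px`.
#' @export
gen_rod_population <- function(n, length_range_um = c(2, 4), aspect = 0.25,
                               orientation_range_deg = c(0, 180),
                               pixel_size_um = 0.02, image_px = NULL,
                               noise_sd = 0, seed = 1L, fg = 180L, bg = 20L,
                               gap_um = 0.1, max_tries = 200L * n) {
  stopifnot(n >= 1L, aspect > 0, aspect <= 1)
  with_seed(seed, {
    Lmax_px <- max(length_range_um) / pixel_size_um
    if (is.null(image_px))
      image_px <- ceiling(sqrt(n) * Lmax_px * 1.15) + 2L * ceiling(Lmax_px)
    side <- as.integer(image_px)
    margin <- Lmax_px / 2 + 2
    placed <- list(); tries <- 0L
    while (length(placed) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        sq_degenerate_error(
          "field too crowded: placed %d of %d rods in %d attempts",
          length(placed), n, max_tries)
      L <- runif(1L, length_range_um[1L], length_range_um[2L]) / pixel_size_um
      W <- aspect * L
      th <- runif(1L, orientation_range_deg[1L],
                  orientation_range_deg[2L]) * pi / 180
      ctr <- runif(2L, margin + 1, side - margin)
      half <- (L - W) / 2
      u <- c(-sin(th), cos(th))  # (drow, dcol); theta from +x axis, y up
      p1 <- ctr - half * u; p2 <- ctr + half * u
      ok <- TRUE
      for (q in placed) {
        mind <- segment_distance(p1, p2, q$p1, q$p2)
        if (mind < (W + q$W) / 2 + gap_um / pixel_size_um) { ok <- FALSE; break }
      }
      if (ok) placed[[length(placed) + 1L]] <-
        list(p1 = p1, p2 = p2, W = W, L = L, theta = th, ctr = ctr)
    }
    mask <- matrix(FALSE, side, side)
    npx <- integer(n)
    for (k in seq_len(n)) {
      r <- placed[[k]]
      stamp <- rasterize_capsule(side, r$p1, r$p2, r$W / 2)
      npx[k] <- nrow(stamp)
      mask[stamp] <- TRUE
    }
    img <- matrix(bg, side, side)
    img[mask] <- fg
    if (noise_sd > 0) {
      img <- img + rnorm(length(img), 0, noise_sd)
      img[] <- pmin(255, pmax(0, round(img)))
    }
    truth <- data.frame(
      object_id = seq_len(n), kind = "rod",
      length_um = vapply(placed, function(r) r$L, numeric(1L)) * pixel_size_um,
      width_um = vapply(placed, function(r) r$W, numeric(1L)) * pixel_size_um,
      aspect = aspect,
      orientation_deg = vapply(placed, function(r) r$theta, numeric(1L)) * 180 / pi,
      center_row = vapply(placed, function(r) r$ctr[1L], numeric(1L)),
      center_col = vapply(placed, function(r) r$ctr[2L], numeric(1L)),
      n_pixels = npx)
    out <- list(
      micrograph = micrograph(img, pixel_size_um, 8L,
                              source_id = sprintf("synthetic_rods_seed%d", seed)),
      mask = binary_mask(mask, pixel_size_um,
                         method_record = list(method = "synthetic", seed = seed)),
      truth = truth)
    attr(out, "seed") <- seed
    attr(out, "n_foreground_px") <- sum(mask)
    out
  })
}

# pixels (row, col) within `radius` of segment p1-p2, inside a side x side canvas
rasterize_capsule <- function(side, p1, p2, radius) {
  rmin <- max(1L, floor(min(p1[1L], p2[1L]) - radius - 1))
  rmax <- min(side, ceiling(max(p1[1L], p2[1L]) + radius + 1))
  cmin <- max(1L, floor(min(p1[2L], p2[2L]) - radius - 1))
  cmax <- min(side, ceiling(max(p1[2L], p2[2L]) + radius + 1))
  rr <- rmin:rmax; cc <- cmin:cmax
  pr <- matrix(rr, length(rr), length(cc))
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  d <- point_segment_distance(pr, pc, p1, p2)
  sel <- which(d <= radius, arr.ind = TRUE)
  cbind(rr[sel[, 1L]], cc[sel[, 2L]])
}

point_segment_distance <- function(pr, pc, p1, p2) {
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) return(sqrt((pr - p1[1L])^2 + (pc - p1[2L])^2))
  t <- ((pr - p1[1L]) * v[1L] + (pc - p1[2L]) * v[2L]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((pr - (p1[1L] + t * v[1L]))^2 + (pc - (p1[2L] + t * v[2L]))^2)
}

# minimum distance between two segments
segment_distance <- function(a1, a2, b1, b2) {
  ts <- seq(0, 1, length.out = 21L)
  pa <- cbind(a1[1L] + ts * (a2[1L] - a1[1L]), a1[2L] + ts * (a2[2L] - a1[2L]))
  d1 <- min(point_segment_distance(pa[, 1L], pa[, 2L], b1, b2))
  pb <- cbind(b1[1L] + ts * (b2[1L] - b1[1L]), b1[2L] + ts * (b2[2L] - b1[2L]))
  d2 <- min(point_segment_distance(pb[, 1L], pb[, 2L], a1, a2))
  min(d1, d2)
}

#' Generate a neuron-like silhouette
#'
#' A soma disc plus arms drawn as thick polylines leaving the soma boundary
#' at stated angles. Tortuosity 0 gives a straight arm; a positive value
#' adds a sinusoidal perpendicular perturbation of that amplitude (in
#' micrometres, two periods along the arm). Ground truth records each arm's
#' geodesic centerline length (soma boundary to tip) and its chord angle.
#' Arms whose silhouettes would overlap outside the soma raise a generation
#' error.
#'
#' @param soma_radius_um soma (cell body) radius.
#' @param arms data frame or list of `c(length_um, angle_deg, tortuosity)`
#'   per arm; angles follow the package convention (degrees from the +x
#'   axis, counterclockwise with y up).
#' @param arm_width_um full width of each arm.
#' @param pixel_size_um calibration (default 0.2 um/px keeps neuron-scale
#'   canvases desk-sized with >= 10 px across an arm of 2 um).
#' @param seed RNG seed (only used for reproducibility bookkeeping; the
#'   pattern itself is deterministic).
#' @param fg,bg intensities for the rendered micrograph.
#' @return List: `micrograph`, `mask`, `truth` (per-arm data frame with
#'   `length_um` = true centerline arc length from soma boundary to tip and
#'   `chord_angle_deg` folded to [0, 90]), `soma` (radius and center).
#' @export
gen_neuron <- function(soma_radius_um = 6, arms = list(), arm_width_um = 2,
                       pixel_size_um = 0.2, seed = 1L, fg = 180L, bg = 20L) {
  if (is.data.frame(arms)) arms <- split(arms, seq_len(nrow(arms)))
  arms <- lapply(arms, function(a) {
    if (is.numeric(a) && is.null(names(a)))
      names(a) <- c("length_um", "angle_deg", "tortuosity")[seq_along(a)]
    a <- as.list(a)
    if (is.null(a$tortuosity)) a$tortuosity <- 0
    a
  })
  s <- pixel_size_um
  r_soma <- soma_radius_um / s
  maxL <- if (length(arms)) max(vapply(arms, function(a)
    a$length_um, numeric(1L))) / s else 0
  half <- ceiling(r_soma + maxL + arm_width_um / s + 6)
  side <- as.integer(2L * half + 1L)
  ctr <- c(half + 1, half + 1)
  mask <- matrix(FALSE, side, side)
  # soma disc
  pr <- matrix(seq_len(side), side, side)
  pc <- t(pr)
  mask[(pr - ctr[1L])^2 + (pc - ctr[2L])^2 <= r_soma^2] <- TRUE
  arm_px <- list()
  truth_rows <- list()
  for (k in seq_along(arms)) {
    a <- arms[[k]]
    L_px <- a$length_um / s
    th <- a$angle_deg * pi / 180
    u <- c(-sin(th), cos(th))       # along-arm unit (drow, dcol), y up
    nrm <- c(-cos(th), -sin(th))    # perpendicular unit
    amp_px <- a$tortuosity / s
    tgrid <- seq(0, L_px, by = 0.25)
    base <- ctr + r_soma * u
    offs <- if (amp_px > 0) amp_px * sin(2 * pi * 2 * tgrid / L_px) else 0
    cl_r <- base[1L] + tgrid * u[1L] + offs * nrm[1L]
    cl_c <- base[2L] + tgrid * u[2L] + offs * nrm[2L]
    arc <- sum(sqrt(diff(cl_r)^2 + diff(cl_c)^2))
    # stamp discs of radius arm_width/2 along the centerline
    stamp <- matrix(FALSE, side, side)
    w2 <- arm_width_um / (2 * s)
    for (i in seq_along(tgrid)) {
      rr <- max(1L, floor(cl_r[i] - w2)):min(side, ceiling(cl_r[i] + w2))
      cc <- max(1L, floor(cl_c[i] - w2)):min(side, ceiling(cl_c[i] + w2))
      sub <- outer((rr - cl_r[i])^2, (cc - cl_c[i])^2, `+`) <= w2^2
      stamp[rr, cc] <- stamp[rr, cc] | sub
    }
    arm_px[[k]] <- stamp
    chord <- c(cl_r[length(cl_r)] - cl_r[1L], cl_c[length(cl_c)] - cl_c[1L])
    ang <- atan2(-chord[1L], chord[2L]) * 180 / pi
    fold <- abs(ang) %% 180; if (fold > 90) fold <- 180 - fold
    truth_rows[[k]] <- data.frame(
      object_id = k, kind = "neurite", length_um = arc * s,
      angle_deg = a$angle_deg, chord_angle_deg = fold,
      tortuosity_amp_um = a$tortuosity)
  }
  # validate: arm silhouettes must not overlap outside the soma
  if (length(arm_px) > 1L) {
    soma_px <- mask
    for (i in seq_len(length(arm_px) - 1L))
      for (j in (i + 1L):length(arm_px))
        if (any(arm_px[[i]] & arm_px[[j]] & !soma_px))
          sq_validation_error("arms %d and %d overlap outside the soma", i, j)
  }
  for (st in arm_px) mask <- mask | st
  img <- matrix(bg, side, side)
  img[mask] <- fg
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else data.frame(object_id = integer(), kind = character(),
                           length_um = numeric(), angle_deg = numeric(),
                           chord_angle_deg = numeric(),
                           tortuosity_amp_um = numeric())
  out <- list(
    micrograph = micrograph(img, s, 8L,
                            source_id = sprintf("synthetic_neuron_seed%d", seed)),
    mask = binary_mask(mask, s, list(method = "synthetic", seed = seed)),
    truth = truth,
    soma = list(radius_um = soma_radius_um, radius_px = r_soma, center = ctr))
  attr(out, "seed") <- seed
  out
}

#' Place several generated neurons on one canvas
#'
#' Tiles single-neuron silhouettes on a grid with clearance so that
#' [label_instances()] recovers exactly one instance per neuron.
#'
#' @param neurons list of [gen_neuron()] results sharing one pixel size.
#' @param pad_px clearance between tiles.
#' @return List: `micrograph`, `mask`, `truth` (row-bound truths with a
#'   `neuron_id` column), `layout` (tile origins).
#' @export
gen_neuron_field <- function(neurons, pad_px = 8L) {
  stopifnot(length(neurons) >= 1L)
  s <- neurons[[1L]]$mask$pixel_size_um
  sizes <- vapply(neurons, function(nn) nrow(nn$mask$pixels), integer(1L))
  tile <- max(sizes) + pad_px
  ncols <- ceiling(sqrt(length(neurons)))
  nrows <- ceiling(length(neurons) / ncols)
  side_r <- nrows * tile + pad_px; side_c <- ncols * tile + pad_px
  mask <- matrix(FALSE, side_r, side_c)
  img <- matrix(20L, side_r, side_c)
  layout <- list(); truths <- list()
  for (k in seq_along(neurons)) {
    gi <- (k - 1L) %/% ncols; gj <- (k - 1L) %% ncols
    r0 <- gi * tile + pad_px; c0 <- gj * tile + pad_px
    mk <- neurons[[k]]$mask$pixels
    rr <- r0 + seq_len(nrow(mk)); cc <- c0 + seq_len(ncol(mk))
    mask[rr, cc] <- mask[rr, cc] | mk
    img[rr, cc] <- neurons[[k]]$micrograph$pixels
    layout[[k]] <- c(row = r0, col = c0)
    tr <- neurons[[k]]$truth
    if (nrow(tr)) tr$neuron_id <- k
    truths[[k]] <- tr
  }
  list(micrograph = micrograph(img, s, 8L, source_id = "synthetic_neuron_field"),
       mask = binary_mask(mask, s, list(method = "synthetic_field")),
       truth = do.call(rbind, truths), layout = layout)
}

#' Generate exact fractal test patterns
#'
#' Deterministic binary patterns with analytically known box-counting
#' dimension: a one-pixel line (D = 1), a filled square (D = 2), and the
#' Sierpinski triangle (D = log 3 / log 2 ~ 1.585). The Sierpinski pattern
#' is built on a 2^iterations grid (pixel (i, j) is foreground iff the
#' bitwise AND of its 0-based coordinates is zero), so its foreground count
#' is exactly 3^iterations.
#'
#' @param pattern one of `"line"`, `"filled_square"`, `"sierpinski"`.
#' @param iterations Sierpinski iteration count (grid = 2^iterations).
#' @param canvas_px canvas edge length for line/filled_square; for
#'   sierpinski the canvas is 2^iterations.
#' @param pixel_size_um calibration carried by the mask.
#' @return List: `mask` ([binary_mask]), `truth` (list with `analytic_D` and
#'   `n_foreground_px`).
#' @export
gen_fractal <- function(pattern = c("line", "filled_square", "sierpinski"),
                        iterations = 8L, canvas_px = 512L,
                        pixel_size_um = 1) {
  pattern <- match.arg(pattern)
  if (pattern == "sierpinski") {
    if (iterations < 1L || iterations > 13L)
      sq_validation_error("sierpinski iterations must be in [1, 13]")
    n <- 2L^iterations
    idx <- 0:(n - 1L)
    px <- outer(idx, idx, function(i, j) bitwAnd(i, j) == 0L)
    D <- log(3) / log(2)
  } else {
    n <- as.integer(canvas_px)
    if (n < 8L) sq_validation_error("canvas too small")
    px <- matrix(FALSE, n, n)
    if (pattern == "line") { px[n %/% 2L, ] <- TRUE; D <- 1 }
    else { px[] <- TRUE; D <- 2 }
  }
  list(mask = binary_mask(px, pixel_size_um,
                          list(method = "synthetic", pattern = pattern)),
       truth = list(pattern = pattern, analytic_D = D,
                    n_foreground_px = sum(px)))
}

#' Generate texture test patterns
#'
#' 8-bit test images for the GLCM module. `constant` and `checkerboard`
#' carry exact expected descriptors in their ground truth (for a symmetric
#' normalized GLCM at offset (0, 1) with levels mapping the two intensities
#' to distinct bins): constant gives ASM 1, entropy 0, contrast 0, IDM 1,
#' correlation undefined; a period-1 checkerboard gives ASM 0.5, entropy
#' ln 2, contrast 1, IDM 0.5, correlation -1.
#'
#' @param kind one of `"constant"`, `"checkerboard"`, `"stripes"`,
#'   `"gaussian_noise"`.
#' @param canvas_px canvas edge length.
#' @param value constant intensity (for `constant`).
#' @param period stripe/checker period in pixels.
#' @param mean_i,sd_i Gaussian noise mean/sd in intensity units.
#' @param pixel_size_um calibration.
#' @param seed RNG seed (used by `gaussian_noise`).
#' @return List: `micrograph`, `truth` (list; includes `expected` descriptor
#'   values where closed-form).
#' @export
gen_texture <- function(kind = c("constant", "checkerboard", "stripes",
                                 "gaussian_noise"),
                        canvas_px = 64L, value = 128L, period = 1L,
                        mean_i = 128, sd_i = 20, pixel_size_um = 1,
                        seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(canvas_px)
  expected <- NULL
  px <- with_seed(seed, switch(kind,
    constant = matrix(as.numeric(value), n, n),
    checkerboard = {
      blk <- (outer(0:(n - 1L) %/% period, 0:(n - 1L) %/% period, `+`)) %% 2L
      blk * 255
    },
    stripes = {
      col_stripe <- ((0:(n - 1L)) %/% period) %% 2L
      matrix(col_stripe * 255, n, n, byrow = TRUE)
    },
    gaussian_noise = matrix(pmin(255, pmax(0, round(
      rnorm(n * n, mean_i, sd_i)))), n, n)))
  if (kind == "constant")
    expected <- list(asm = 1, entropy = 0, contrast = 0, idm = 1,
                     correlation = NA_real_)
  if (kind == "checkerboard" && period == 1L)
    expected <- list(asm = 0.5, entropy = log(2), contrast = 1, idm = 0.5,
                     correlation = -1)
  list(micrograph = micrograph(px, pixel_size_um, 8L,
                               source_id = sprintf("synthetic_%s", kind)),
       truth = list(kind = kind, period = period, expected = expected,
                    seed = seed))
}
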