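# Gray-level co-occurrence matrix (GLCM) texture descriptors in the Haralick
# convention: angular second moment, entropy, contrast, correlation, and
# inverse difference moment.

#' Quantize a micrograph for GLCM analysis
#'
#' Intensities are mapped to `{0, ..., levels - 1}` by uniform binning over
#' the full bit-depth range (not the observed min-max), so descriptors remain
#' comparable across images from one acquisition session.
#'
#' @param m a [micrograph] (or a plain intensity matrix together with
#'   `bit_depth`).
#' @param levels number of gray levels (>= 2).
#' @param bit_depth used when `m` is a bare matrix.
#' @return Integer matrix of levels in `{0, ..., levels - 1}`.
#' @export
quantize <- function(m, levels = 16L, bit_depth = 8L) {
  if (levels < 2L) sq_validation_error("levels must be >= 2")
  px <- if (inherits(m, "micrograph")) { bit_depth <- m$bit_depth; m$pixels }
        else m
  q <- floor(px * levels / 2^bit_depth)
  q[q > levels - 1L] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' GLCM configuration
#'
#' @param levels quantization level count (>= 2).
#' @param offsets list of `c(drow, dcol)` displacement vectors (nonzero). The
#'   default `{(0,1), (1,0), (1,1), (1,-1)}` accumulates the four standard
#'   distance-1 directions for rotation-tolerant descriptors.
#' @param symmetric add the transposed counts (order-independent pairs).
#' @param normalize scale counts to sum to 1.
#' @return List of class `glcm_config`.
#' @export
glcm_config <- function(levels = 16L,
                        offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L),
                                       c(1L, -1L)),
                        symmetric = TRUE, normalize = TRUE) {
  if (levels < 2L) sq_validation_error("levels must be >= 2")
  for (o in offsets)
    if (length(o) != 2L || all(o == 0L))
      sq_validation_error("each offset must be a nonzero (drow, dcol) pair")
  structure(list(levels = as.integer(levels), offsets = offsets,
                 symmetric = symmetric, normalize = normalize),
            class = "glcm_config")
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized levels at each displacement, summed
#' over the configured offsets, optionally symmetrized and normalized to a
#' probability matrix.
#'
#' @param q integer matrix of quantized levels (from [quantize()]).
#' @param config a [glcm_config()].
#' @return `levels x levels` matrix `p(i, j)`, rows/cols indexed by level
#'   0-based.
#' @export
glcm <- function(q, config = glcm_config()) {
  stopifnot(is.matrix(q))
  L <- config$levels
  if (any(q < 0L) || any(q > L - 1L))
    sq_validation_error("quantized values outside [0, levels-1]")
  nr <- nrow(q); nc <- ncol(q)
  G <- matrix(0, L, L)
  for (off in config$offsets) {
    dr <- off[1L]; dc <- off[2L]
    if (abs(dr) >= nr || abs(dc) >= nc)
      sq_validation_error("offset (%d, %d) exceeds image size", dr, dc)
    r1 <- max(1L, 1L - dr):min(nr, nr - dr)
    c1 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    idx <- as.vector(a) * L + as.vector(b) + 1L
    cnt <- tabulate(idx, nbins = L * L)
    G <- G + matrix(cnt, L, L, byrow = TRUE)
  }
  if (config$symmetric) G <- G + t(G)
  if (config$normalize) G <- G / sum(G)
  dimnames(G) <- list(0:(L - 1L), 0:(L - 1L))
  G
}

#' Haralick descriptors of a normalized GLCM
#'
#' For a normalized co-occurrence matrix p(i, j) over levels i, j:
#' \itemize{
#' \item angular second moment (ASM): sum of p^2 (1 for a single-valued
#'   image, small for uniform textures);
#' \item entropy: -sum p log p in natural log (0 log 0 := 0; a log2 option
#'   is available for comparability);
#' \item contrast: sum (i - j)^2 p;
#' \item correlation: sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j), in
#'   [-1, 1]; undefined (reported `NA` with an attribute) for a constant
#'   image where sigma = 0;
#' \item inverse difference moment (IDM): sum p / (1 + (i - j)^2).
#' }
#'
#' @param P normalized GLCM (sums to 1).
#' @param entropy_base `"nat"` (default) or `"log2"`.
#' @return List of class `glcm_descriptors`: `asm`, `entropy`, `contrast`,
#'   `correlation`, `idm`.
#' @export
glcm_descriptors <- function(P, entropy_base = c("nat", "log2")) {
  entropy_base <- match.arg(entropy_base)
  if (!is.matrix(P) || nrow(P) != ncol(P))
    sq_validation_error("P must be a square matrix")
  if (abs(sum(P) - 1) > 1e-8)
    sq_validation_error("GLCM must be normalized (sum = 1); got sum = %g", sum(P))
  L <- nrow(P)
  i <- matrix(0:(L - 1L), L, L)          # row level index
  j <- t(i)
  asm <- sum(P^2)
  nz <- P > 0
  ent <- -sum(P[nz] * log(P[nz]))
  if (entropy_base == "log2") ent <- ent / log(2)
  contrast <- sum((i - j)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mui <- sum((0:(L - 1L)) * pi_); muj <- sum((0:(L - 1L)) * pj_)
  vi <- sum((0:(L - 1L) - mui)^2 * pi_); vj <- sum((0:(L - 1L) - muj)^2 * pj_)
  correlation <- if (vi <= 0 || vj <= 0) {
    structure(NA_real_, reason = "undefined: zero gray-level variance")
  } else sum((i - mui) * (j - muj) * P) / sqrt(vi * vj)
  structure(list(asm = asm, entropy = ent, contrast = contrast,
                 correlation = correlation, idm = idm),
            class = "glcm_descriptors")
}

#' @export
print.glcm_descriptors <- function(x, ...) {
  cat(sprintf(
    "<glcm_descriptors> ASM %.4f | entropy %.4f | contrast %.4f | corr %s | IDM %.4f\n",
    x$asm, x$entropy, x$contrast,
    if (is.na(x$correlation)) "undef" else sprintf("%.4f", x$correlation),
    x$idm))
  invisible(x)
}

#' Whole-image GLCM descriptors
#'
#' Convenience wrapper: quantize, accumulate the GLCM, and compute the five
#' descriptors.
#'
#' @param m a [micrograph].
#' @param config a [glcm_config()].
#' @inheritParams glcm_descriptors
#' @return A `glcm_descriptors` list.
#' @export
texture_descriptors <- function(m, config = glcm_config(),
                                entropy_base = "nat") {
  q <- quantize(m, config$levels)
  glcm_descriptors(glcm(q, config), entropy_base)
}

#' Sliding-window texture maps
#'
#' Evaluates the five GLCM descriptors in a window glided over the image,
#' producing one raster per descriptor. These per-window features are what a
#' downstream texture classifier would consume; classification itself is out
#' of scope here.
#'
#' @param m a [micrograph].
#' @param window_px window edge length (>= 3, <= image).
#' @param stride_px window step.
#' @param config a [glcm_config()].
#' @return List: `origins` (data frame of window top-left row/col), `maps`
#'   (named list of matrices, one per descriptor, indexed by window grid
#'   position).
#' @export
texture_map <- function(m, window_px = 64L, stride_px = 32L,
                        config = glcm_config()) {
  stopifnot(inherits(m, "micrograph"))
  nr <- nrow(m$pixels); nc <- ncol(m$pixels)
  if (window_px < 3L) sq_validation_error("window must be >= 3 px")
  if (window_px > nr || window_px > nc)
    sq_validation_error("window (%d px) exceeds image (%d x %d)",
                        window_px, nr, nc)
  q <- quantize(m, config$levels)
  r0 <- seq(1L, nr - window_px + 1L, by = stride_px)
  c0 <- seq(1L, nc - window_px + 1L, by = stride_px)
  desc_names <- c("asm", "entropy", "contrast", "correlation", "idm")
  maps <- lapply(desc_names, function(d) matrix(NA_real_, length(r0), length(c0)))
  names(maps) <- desc_names
  for (a in seq_along(r0)) for (b in seq_along(c0)) {
    win <- q[r0[a]:(r0[a] + window_px - 1L), c0[b]:(c0[b] + window_px - 1L)]
    d <- glcm_descriptors(glcm(win, config))
    for (nm in desc_names) maps[[nm]][a, b] <- as.numeric(d[[nm]])
  }
  origins <- expand.grid(row = r0, col = c0, KEEP.OUT.ATTRS = FALSE)
  list(origins = origins, maps = maps,
       window_px = as.integer(window_px), stride_px = as.integer(stride_px))
}
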