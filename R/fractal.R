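# Fractal descriptors of binary silhouettes: box-counting dimension D and
# gliding-box lacunarity.

#' Box counts of a binary mask
#'
#' For each box size, counts the number of boxes of an axis-aligned grid that
#' contain at least one foreground pixel, minimized over `n_offsets` diagonal
#' grid translations (reduces the grid-phase bias of single-origin counting).
#'
#' @param mask a [binary_mask] or logical matrix.
#' @param sizes integer vector of box edge lengths in pixels (each >= 1 and
#'   <= the smaller image dimension).
#' @param n_offsets number of diagonal grid translations (>= 1).
#' @return Integer vector of N(eps), one per size.
#' @export
box_count <- function(mask, sizes, n_offsets = 4L) {
  px <- mask_pixels(mask)
  if (!any(px)) sq_degenerate_error("empty mask: box count undefined")
  if (any(sizes < 1L) || any(sizes > min(dim(px))))
    sq_validation_error("box sizes must lie in [1, min(image dims)]")
  fg <- which(px, arr.ind = TRUE) - 1L  # 0-based
  vapply(as.integer(sizes), function(eps) {
    offs <- floor((seq_len(n_offsets) - 1L) * eps / n_offsets)
    min(vapply(offs, function(o) {
      br <- (fg[, 1L] + o) %/% eps
      bc <- (fg[, 2L] + o) %/% eps
      length(unique(br * (max(bc) + 1L) + bc))
    }, numeric(1L)))
  }, numeric(1L))
}

mask_pixels <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$pixels
  else if (is.matrix(mask) && is.logical(mask)) mask
  else if (is.matrix(mask)) mask > 0
  else sq_validation_error("mask must be a binary_mask or matrix")
}

default_box_sizes <- function(px) {
  mx <- floor(min(dim(px)) / 4)
  if (mx < 2L) sq_validation_error("image too small for box counting")
  2^(1:floor(log2(mx)))
}

#' Box-counting fractal dimension
#'
#' D is a statistical index of structural complexity: how the detail of a
#' silhouette changes with the scale at which it is measured. It is estimated
#' as the least-squares slope of log N(eps) against log(1/eps) over a range
#' of box sizes (default: powers of 2 from 2 px up to a quarter of the
#' smaller image dimension). Simple silhouettes give small D; highly branched
#' ones approach 2.
#'
#' @inheritParams box_count
#' @param sizes box sizes; default as described above. At least 4 sizes are
#'   required for a meaningful fit.
#' @return List of class `fractal_result`: `box_sizes_px`, `box_counts`,
#'   `dimension_D`, `fit_intercept`, `fit_r2`, `n_offsets_averaged`. A
#'   warning is raised when the log-log fit has R^2 < 0.98 (poor scaling
#'   regime).
#' @export
fractal_dimension <- function(mask, sizes = NULL, n_offsets = 4L) {
  px <- mask_pixels(mask)
  if (is.null(sizes)) sizes <- default_box_sizes(px)
  sizes <- sort(as.integer(sizes), decreasing = TRUE)
  if (length(sizes) < 4L)
    sq_validation_error("need >= 4 box sizes for the log-log fit (got %d)",
                        length(sizes))
  N <- box_count(px, sizes, n_offsets)
  fit <- lm(log(N) ~ log(1 / sizes))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  if (is.na(r2)) r2 <- 0
  if (r2 < 0.98)
    warning(sprintf("poor scaling regime: log-log fit R^2 = %.3f", r2),
            call. = FALSE)
  structure(list(box_sizes_px = sizes, box_counts = N,
                 dimension_D = unname(coef(fit)[2L]),
                 fit_intercept = unname(coef(fit)[1L]),
                 fit_r2 = r2, n_offsets_averaged = as.integer(n_offsets)),
            class = "fractal_result")
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("<fractal_result> D = %.4f (R^2 = %.4f), %d box sizes\n",
              x$dimension_D, x$fit_r2, length(x$box_sizes_px)))
  invisible(x)
}

#' Gliding-box lacunarity
#'
#' Lacunarity measures how a pattern fills the available space: the gaps, or
#' heterogeneity, at each scale. For each box size r, the foreground mass M
#' is collected in a box glided over every position (or over a
#' non-overlapping grid when `mode = "grid"`), and
#' \deqn{\Lambda(r) = \mathrm{var}(M)/\mathrm{mean}(M)^2 + 1
#'   = E[M^2]/E[M]^2,}
#' so a translationally uniform mass distribution has lacunarity exactly 1
#' and clumped patterns score higher.
#'
#' @inheritParams box_count
#' @param box_sizes box edge lengths in pixels.
#' @param mode `"gliding"` (all positions, default) or `"grid"`
#'   (non-overlapping tiling).
#' @return List of class `lacunarity_result`: `box_sizes_px`, `lambda_curve`,
#'   `mean_lambda`.
#' @export
lacunarity <- function(mask, box_sizes = NULL, mode = c("gliding", "grid")) {
  mode <- match.arg(mode)
  px <- mask_pixels(mask)
  if (!any(px)) sq_degenerate_error("empty mask: lacunarity undefined")
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(px)
  box_sizes <- as.integer(box_sizes)
  if (any(box_sizes < 1L) || any(box_sizes > min(dim(px))))
    sq_validation_error("box sizes must fit within the image")
  S <- apply(apply(px * 1L, 2L, cumsum), 1L, cumsum)  # transposed integral
  S <- t(S)
  S <- rbind(0, cbind(0, S))  # S[i+1, j+1] = sum px[1..i, 1..j]
  nr <- nrow(px); nc <- ncol(px)
  lam <- vapply(box_sizes, function(r) {
    if (mode == "gliding") {
      i0 <- 0:(nr - r); j0 <- 0:(nc - r)
    } else {
      i0 <- seq(0L, nr - r, by = r); j0 <- seq(0L, nc - r, by = r)
    }
    M <- S[i0 + r + 1L, j0 + r + 1L, drop = FALSE] -
         S[i0 + 1L, j0 + r + 1L, drop = FALSE] -
         S[i0 + r + 1L, j0 + 1L, drop = FALSE] +
         S[i0 + 1L, j0 + 1L, drop = FALSE]
    mean(M^2) / mean(M)^2
  }, numeric(1L))
  structure(list(box_sizes_px = box_sizes, lambda_curve = lam,
                 mean_lambda = mean(lam), mode = mode),
            class = "lacunarity_result")
}

#' @export
print.lacunarity_result <- function(x, ...) {
  cat(sprintf("<lacunarity_result> mean lambda = %.4f over %d box sizes (%s)\n",
              x$mean_lambda, length(x$box_sizes_px), x$mode))
  invisible(x)
}

#' Threshold-to-fractal silhouette pipeline
#'
#' The standard workflow for fractal quantification of micrographs:
#' threshold, clean to a binary silhouette, optionally reduce to the outline,
#' then compute both the box-counting dimension and the lacunarity curve.
#' Whether the analysis ran on the filled silhouette or the outline, and on
#' the whole field or border-excluded cells, is recorded in the result.
#'
#' @param m a [micrograph] (or a ready [binary_mask], in which case
#'   thresholding is skipped).
#' @param mode `"silhouette"` (filled shapes, default) or `"outline"`
#'   (one-pixel boundary).
#' @param threshold_method,manual_threshold,invert passed to [binarize()].
#' @param min_object_px,fill_holes passed to [clean_mask()].
#' @param sizes,n_offsets passed to the descriptor functions.
#' @return List: `mask` (the analyzed [binary_mask]), `fractal`
#'   ([fractal_dimension()] result), `lacunarity` ([lacunarity()] result),
#'   `mode`.
#' @export
silhouette_pipeline <- function(m, mode = c("silhouette", "outline"),
                                threshold_method = "otsu",
                                manual_threshold = NULL, invert = FALSE,
                                min_object_px = 0L, fill_holes = FALSE,
                                sizes = NULL, n_offsets = 4L) {
  mode <- match.arg(mode)
  mask <- if (inherits(m, "binary_mask")) m
          else clean_mask(binarize(m, threshold_method, manual_threshold,
                                   invert),
                          min_object_px, fill_holes)
  px <- mask$pixels
  if (mode == "outline") px <- outline_pixels(px)
  amask <- binary_mask(px, mask$pixel_size_um, mask$method_record)
  list(mask = amask,
       fractal = fractal_dimension(px, sizes, n_offsets),
       lacunarity = lacunarity(px, sizes),
       mode = mode)
}

# 1-px outline: foreground pixels with at least one 4-neighbour background
outline_pixels <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- px
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  interior <- p[ri, ci] & p[ri - 1L, ci] & p[ri + 1L, ci] &
              p[ri, ci - 1L] & p[ri, ci + 1L]
  px & !interior
}
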