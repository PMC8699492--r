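test_that("box counts are exact on aligned tilings", {
  sq <- matrix(FALSE, 80, 80); sq[1:64, 1:64] <- TRUE
  expect_equal(box_count(sq, 8, n_offsets = 1L), 64)
  single <- matrix(FALSE, 32, 32); single[17, 9] <- TRUE
  for (eps in c(2, 4, 8)) expect_equal(box_count(single, eps), 1)
  line <- matrix(FALSE, 64, 64); line[1, 1:64] <- TRUE
  expect_equal(box_count(line, 8, n_offsets = 1L), 8)
  expect_error(box_count(matrix(FALSE, 8, 8), 2),
               class = "semquant_degenerate_error")
  expect_error(box_count(sq, 100), class = "semquant_validation_error")
})

test_that("N(eps) is non-increasing in eps and offset minimization never increases it", {
  syn <- gen_neuron(6, list(c(30, 15, 0), c(25, 130, 1)), pixel_size_um = 0.2)
  px <- syn$mask$pixels
  sizes <- c(64, 32, 16, 8, 4, 2)
  N <- box_count(px, sizes)
  expect_true(all(diff(N) >= 0))  # counts grow as boxes shrink
  N1 <- box_count(px, sizes, n_offsets = 1L)
  N8 <- box_count(px, sizes, n_offsets = 8L)
  expect_true(all(N8 <= N1))
})

test_that("known-dimension suite: line 1, filled square 2, Sierpinski log3/log2", {
  line <- gen_fractal("line", canvas_px = 512)
  f1 <- fractal_dimension(line$mask)
  expect_equal(f1$dimension_D, 1, tolerance = 0.05)
  expect_gte(f1$fit_r2, 0.98)
  sq <- gen_fractal("filled_square", canvas_px = 512)
  f2 <- fractal_dimension(sq$mask)
  expect_equal(f2$dimension_D, 2, tolerance = 0.05)
  expect_gte(f2$fit_r2, 0.98)
  sier <- gen_fractal("sierpinski", iterations = 7)
  f3 <- fractal_dimension(sier$mask)
  expect_equal(f3$dimension_D, log(3) / log(2), tolerance = 0.05)
  expect_gte(f3$fit_r2, 0.98)
  expect_error(fractal_dimension(line$mask, sizes = c(2, 4, 8)),
               class = "semquant_validation_error")
})

test_that("D is invariant under translation and 90-degree rotation", {
  sier <- gen_fractal("sierpinski", iterations = 7)$mask$pixels
  pad <- matrix(FALSE, 160, 160)
  pad[10:(9 + nrow(sier)), 20:(19 + ncol(sier))] <- sier
  d0 <- fractal_dimension(pad)$dimension_D
  shifted <- matrix(FALSE, 160, 160)
  shifted[25:(24 + nrow(sier)), 5:(4 + ncol(sier))] <- sier
  expect_equal(fractal_dimension(shifted)$dimension_D, d0, tolerance = 0.05)
  rot <- t(pad)[ncol(pad):1, ]
  expect_equal(fractal_dimension(rot)$dimension_D, d0, tolerance = 0.05)
})

test_that("lacunarity matches the brute-force gliding-box oracle", {
  set.seed(31)
  px <- matrix(runif(64 * 64) > 0.8, 64, 64)
  for (r in c(4, 8)) {
    lam <- lacunarity(px, r)$lambda_curve
    expect_equal(lam, lacunarity_oracle(px, r), tolerance = 1e-12)
  }
})

test_that("lacunarity is 1 for uniform mass and ranks clustering correctly", {
  expect_identical(lacunarity(matrix(TRUE, 32, 32), c(2, 4, 8))$lambda_curve,
                   c(1, 1, 1))
  # checkerboard sampled at one full period carries constant box mass
  check <- (outer(0:31, 0:31, `+`) %% 2L) == 0L
  expect_equal(lacunarity(check, 2)$lambda_curve, 1, tolerance = 1e-12)
  blob <- matrix(FALSE, 64, 64); blob[29:36, 29:36] <- TRUE
  set.seed(5)
  scat <- matrix(FALSE, 64, 64); scat[sample(64 * 64, 64)] <- TRUE
  l_blob <- lacunarity(blob, 8)$lambda_curve
  l_scat <- lacunarity(scat, 8)$lambda_curve
  expect_gt(l_blob, l_scat)
  expect_gte(l_scat, 1)
  expect_error(lacunarity(matrix(FALSE, 8, 8), 2),
               class = "semquant_degenerate_error")
})

test_that("lambda decreases toward 1 as the box approaches the image size", {
  syn <- gen_neuron(5, list(c(20, 40, 0)), pixel_size_um = 0.2)
  px <- syn$mask$pixels
  sizes <- c(4, 16, 64, min(dim(px)) - 1)
  lam <- lacunarity(px, sizes)$lambda_curve
  expect_true(all(diff(lam) < 0))
  expect_gte(lam[length(lam)], 1)
  expect_lt(lam[length(lam)], 1.1)
})

test_that("silhouette pipeline is consistent end-to-end and ranks branching by D", {
  syn <- gen_neuron(6, list(c(30, 25, 0), c(28, 150, 0)), pixel_size_um = 0.2)
  res <- silhouette_pipeline(syn$micrograph)
  direct <- fractal_dimension(syn$mask$pixels,
                              sizes = res$fractal$box_sizes_px)
  expect_equal(res$fractal$dimension_D, direct$dimension_D, tolerance = 1e-9)
  # outline of a filled disc is a curve: D ~ 1
  disc <- binary_mask(disc_matrix(100, pad = 14), 1)
  out <- silhouette_pipeline(disc, mode = "outline")
  expect_equal(out$fractal$dimension_D, 1, tolerance = 0.1)
  # higher branching -> larger D, compared on a common canvas and size range
  embed <- function(px, side) {
    out <- matrix(FALSE, side, side)
    r0 <- (side - nrow(px)) %/% 2L; c0 <- (side - ncol(px)) %/% 2L
    out[r0 + seq_len(nrow(px)), c0 + seq_len(ncol(px))] <- px
    out
  }
  star <- function(narms, tort) {
    angs <- seq(0, 360, length.out = narms + 1)[seq_len(narms)] + 5
    gen_neuron(2, lapply(angs, function(a) c(35, a, tort)),
               arm_width_um = 0.8, pixel_size_um = 0.2)
  }
  lo <- star(1, 0); hi <- star(12, 1)
  side <- max(dim(lo$mask$pixels), dim(hi$mask$pixels)) + 20L
  sizes <- 2^(1:6)
  d_lo <- fractal_dimension(embed(lo$mask$pixels, side), sizes)$dimension_D
  d_hi <- fractal_dimension(embed(hi$mask$pixels, side), sizes)$dimension_D
  expect_gt(d_hi, d_lo)
})
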