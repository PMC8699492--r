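test_that("quantization maps endpoints, midpoints, and constants as documented", {
  m <- micrograph(matrix(c(0, 255, 128, 64), 2, 2), 1)
  q <- quantize(m, 8)
  expect_identical(sort(unique(as.vector(q))), c(0L, 2L, 4L, 7L))
  expect_identical(q[1, 2], 4L)  # floor(128 * 8 / 256)
  expect_identical(unique(as.vector(quantize(micrograph(matrix(99, 4, 4), 1), 16))),
                   6L)  # floor(99 * 16 / 256)
  expect_error(quantize(m, 1), class = "semquant_validation_error")
})

test_that("GLCM matches a brute-force pair-enumeration oracle", {
  set.seed(17)
  q <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L))
  cfg <- glcm_config(levels = 4L, offsets = offs)
  expect_equal(unname(glcm(q, cfg)), glcm_oracle(q, 4L, offs), tolerance = 1e-12)
})

test_that("constant and checkerboard images give their analytic GLCMs", {
  const <- matrix(5L, 6, 6)
  cfg <- glcm_config(levels = 8L, offsets = list(c(0L, 1L)))
  P <- glcm(const, cfg)
  expect_equal(P[6, 6], 1)
  expect_equal(sum(P), 1)
  check <- quantize(gen_texture("checkerboard", canvas_px = 16,
                                period = 1)$micrograph, 2)
  P2 <- glcm(check, glcm_config(levels = 2L, offsets = list(c(0L, 1L))))
  expect_equal(unname(P2), matrix(c(0, 0.5, 0.5, 0), 2, 2), tolerance = 1e-12)
  # symmetric GLCMs equal their transpose
  set.seed(3)
  qr <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
  Ps <- glcm(qr, glcm_config(levels = 8L))
  expect_equal(Ps, t(Ps), tolerance = 1e-12)
  expect_error(glcm(qr, glcm_config(levels = 8L, offsets = list(c(0L, 50L)))),
               class = "semquant_validation_error")
})

test_that("descriptors reproduce the analytic constant/checkerboard suite", {
  d0 <- glcm_descriptors(glcm(matrix(2L, 8, 8),
                              glcm_config(levels = 4L, offsets = list(c(0L, 1L)))))
  expect_identical(d0$asm, 1)
  expect_identical(d0$entropy, 0)
  expect_identical(d0$contrast, 0)
  expect_identical(d0$idm, 1)
  expect_true(is.na(d0$correlation))  # undefined, flagged not NaN
  expect_match(attr(d0$correlation, "reason"), "zero gray-level variance")
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  d <- glcm_descriptors(P)
  expect_equal(d$asm, 0.5, tolerance = 1e-15)
  expect_equal(d$entropy, log(2), tolerance = 1e-15)
  expect_equal(d$contrast, 1, tolerance = 1e-15)
  expect_equal(d$idm, 0.5, tolerance = 1e-15)
  expect_equal(as.numeric(d$correlation), -1, tolerance = 1e-12)
  expect_equal(glcm_descriptors(P, entropy_base = "log2")$entropy, 1,
               tolerance = 1e-15)
  expect_error(glcm_descriptors(P * 2), class = "semquant_validation_error")
})

test_that("descriptors are invariant under transpose and sub-quantization shifts", {
  set.seed(23)
  px <- matrix(sample(0:255, 1024, replace = TRUE), 32, 32)
  m <- micrograph(px, 1)
  d1 <- texture_descriptors(m, glcm_config(levels = 16L))
  dT <- glcm_descriptors(t(glcm(quantize(m, 16), glcm_config(levels = 16L))))
  expect_equal(unlist(d1), unlist(dT), tolerance = 1e-12)
  # adding a constant below one quantization bin (16 levels -> bin = 16) to
  # values away from bin edges leaves all descriptors unchanged
  px2 <- (px %/% 16) * 16 + 4
  m2 <- micrograph(px2, 1)
  m3 <- micrograph(px2 + 7, 1)
  expect_equal(unlist(texture_descriptors(m2)), unlist(texture_descriptors(m3)),
               tolerance = 1e-12)
})

test_that("entropy and ASM oppose monotonically along a noise sweep", {
  ent <- c(); asm <- c()
  for (sdv in c(0.5, 8, 32, 80)) {
    tx <- gen_texture("gaussian_noise", canvas_px = 96, sd_i = sdv, seed = 11)
    d <- texture_descriptors(tx$micrograph)
    ent <- c(ent, d$entropy); asm <- c(asm, d$asm)
  }
  expect_true(all(diff(ent) > 0))
  expect_true(all(diff(asm) < 0))
  expect_lt(ent[length(ent)], log(16^2))  # bounded by uniform-pair entropy
})

test_that("texture maps separate halves of different variance and stay consistent", {
  set.seed(2)
  half <- function(sdv) matrix(pmin(255, pmax(0, round(rnorm(64 * 32, 128, sdv)))),
                               64, 32)
  m <- micrograph(cbind(half(4), half(45)), 1)
  tm <- texture_map(m, window_px = 16, stride_px = 16)
  left <- tm$maps$contrast[, 1:2]; right <- tm$maps$contrast[, 3:4]
  expect_gt(min(right), 10 * max(left))  # bimodal, separable by threshold
  # window = image reproduces the whole-image descriptors
  tm1 <- texture_map(m, window_px = 64, stride_px = 64)
  whole <- texture_descriptors(m)
  expect_equal(tm1$maps$asm[1, 1], whole$asm, tolerance = 1e-12)
  # constant image: every map cell equal
  tmc <- texture_map(micrograph(matrix(80, 64, 64), 1), 16, 16)
  expect_equal(var(as.vector(tmc$maps$entropy)), 0)
  expect_error(texture_map(m, window_px = 128), class = "semquant_validation_error")
})
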