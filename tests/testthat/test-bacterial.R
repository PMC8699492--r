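test_that("spherocylinder volume matches hand-evaluated values and the sphere limit", {
  # sphere limit V(d, d) = pi d^3 / 6, machine precision
  for (d in c(0.5, 1, 2.7))
    expect_equal(rod_volume(d, d), pi * d^3 / 6, tolerance = 1e-15)
  # frozen hand evaluations of (pi W^2 / 4)(L - W/3)
  expect_equal(rod_volume(2.0, 0.5), 0.35997415822383046, tolerance = 1e-12)
  expect_equal(rod_volume(4, 1), 2.8797932657906435, tolerance = 1e-12)
  expect_error(rod_volume(1, 2), class = "semquant_validation_error")
  expect_error(rod_volume(-1, -2), class = "semquant_validation_error")
})

test_that("volume is monotone in L and W, and S/V decreases with length", {
  L <- seq(1, 5, by = 0.25)
  v_L <- rod_volume(L, 0.8)
  expect_true(all(diff(v_L) > 0))
  W <- seq(0.2, 2, by = 0.1)
  v_W <- rod_volume(2, W)
  expect_true(all(diff(v_W) > 0))
  sv <- rod_surface(L, 0.8) / rod_volume(L, 0.8)
  expect_true(all(diff(sv) < 0))
})

test_that("model surface has the sphere limit and S/V = 6/d for spheres", {
  expect_equal(rod_surface(1, 1), pi, tolerance = 1e-15)
  expect_equal(rod_surface(2, 0.5), pi, tolerance = 1e-15)
  expect_equal(rod_surface(1, 1) / rod_volume(1, 1), 6, tolerance = 1e-12)
})

test_that("aspect ratio is W/L, scale-invariant, and clips noise above 1", {
  expect_equal(aspect_ratio(1, 1), 1)
  expect_equal(aspect_ratio(1, 4), 0.25)
  expect_equal(aspect_ratio(0.5, 2.0), 0.25)
  expect_warning(r <- aspect_ratio(1.01, 1), "clipped")
  expect_equal(r, 1)
  expect_error(aspect_ratio(0, 1), class = "semquant_validation_error")
})

test_that("measure_rod recovers single-rod geometry within 5%", {
  syn <- gen_rod_population(1, length_range_um = c(3, 3), aspect = 0.8 / 3,
                            seed = 5, image_px = 300)
  cell <- label_instances(syn$mask)[[1L]]
  m <- measure_rod(cell, 0.02)
  expect_equal(m$length_um, 3.0, tolerance = 0.05)
  expect_equal(m$width_um, 0.8, tolerance = 0.05)
  # analytic capsule area: W(L-W) + pi (W/2)^2
  a_true <- 0.8 * (3 - 0.8) + pi * 0.4^2
  expect_equal(m$projected_area_um2, a_true, tolerance = 0.05)
})

test_that("a disc measures length ~ width ~ diameter; a square's area is exact", {
  cell <- as_instance(disc_matrix(40), pixel_size_um = 0.1)
  m <- measure_rod(cell, 0.1)
  expect_equal(m$length_um, 8, tolerance = 0.05)
  expect_equal(m$width_um, 8, tolerance = 0.05)
  sq <- matrix(FALSE, 30, 30); sq[11:20, 11:20] <- TRUE
  msq <- measure_rod(as_instance(sq, 0.1), 0.1)
  expect_equal(msq$projected_area_um2, 1.0, tolerance = 1e-12)
})

test_that("measurements scale with calibration: k-fold lengths, k^2 areas, k^3 volumes", {
  syn <- gen_rod_population(1, length_range_um = c(2.5, 2.5), seed = 9,
                            image_px = 300)
  cell <- label_instances(syn$mask)[[1L]]
  m1 <- measure_rod(cell, 0.02)
  m2 <- measure_rod(cell, 0.04)
  expect_equal(m2$length_um / m1$length_um, 2, tolerance = 1e-12)
  expect_equal(m2$width_um / m1$width_um, 2, tolerance = 1e-12)
  expect_equal(m2$projected_area_um2 / m1$projected_area_um2, 4, tolerance = 1e-12)
  v1 <- rod_volume(m1$length_um, m1$width_um)
  v2 <- rod_volume(m2$length_um, m2$width_um)
  expect_equal(v2 / v1, 8, tolerance = 1e-12)
})

test_that("Feret cross-check agrees with medial-axis estimates on straight rods", {
  syn <- gen_rod_population(1, length_range_um = c(3.2, 3.2), seed = 13,
                            image_px = 300)
  cell <- label_instances(syn$mask)[[1L]]
  m <- measure_rod(cell, 0.02, feret = TRUE)
  expect_equal(m$feret_length_um, m$length_um, tolerance = 0.05)
  expect_equal(m$feret_width_um, m$width_um, tolerance = 0.07)
})

test_that("population summaries recover generator truth and keep filter bookkeeping", {
  syn <- gen_rod_population(30, seed = 21)
  cells <- label_instances(syn$mask)
  pop <- measure_population(cells, 0.02, source_id = "pop")
  expect_equal(nrow(pop$per_cell), 30L)
  # sample mean within 3 SE of generator truth
  se <- sd(syn$truth$length_um) / sqrt(30)
  expect_lt(abs(mean(pop$per_cell$length_um) - mean(syn$truth$length_um)), 3 * se + 0.05)
  expect_lt(abs(mean(pop$per_cell$aspect_ratio) - 0.25), 0.02)
  expect_s3_class(pop$table, "result_table")
  expect_true(all(c("mean", "sd", "n") %in% names(pop$summary)))
  # a too-small speck among the cells is skipped, not fatal
  px <- matrix(FALSE, 40, 40); px[5:30, 5:10] <- TRUE; px[35, 35] <- TRUE
  cells2 <- label_instances(binary_mask(px, 0.1))
  pop2 <- measure_population(cells2, 0.1)
  expect_equal(unique(pop2$summary$n), 1L)
  expect_equal(nrow(pop2$skipped), 1L)
  expect_match(pop2$skipped$reason, "too small")
  expect_error(measure_population(list(), 0.1), class = "semquant_degenerate_error")
})

test_that("identical rods give zero population spread", {
  syn <- gen_rod_population(4, length_range_um = c(3, 3), seed = 2,
                            image_px = 700)
  pop <- measure_population(label_instances(syn$mask), 0.02)
  # all rods congruent up to rotation; rasterization makes sd tiny, not 0
  expect_lt(pop$summary$sd[pop$summary$descriptor == "projected_area_um2"] /
            pop$summary$mean[pop$summary$descriptor == "projected_area_um2"], 0.02)
})
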