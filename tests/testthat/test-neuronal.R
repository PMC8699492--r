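test_that("soma is the maximal inscribed disc: disc, generated neuron, rectangle", {
  cell <- as_instance(disc_matrix(25), 1)
  soma <- identify_soma(cell)
  expect_equal(soma$diameter_um, 50, tolerance = 1 / 50)
  syn <- gen_neuron(soma_radius_um = 6,
                    arms = list(c(20, 30, 0)), pixel_size_um = 0.2)
  s2 <- identify_soma(label_instances(syn$mask)[[1L]])
  expect_equal(s2$diameter_um / 0.2, 60, tolerance = 2 / 60)  # 60 px +/- 2
  rect <- matrix(FALSE, 40, 70); rect[11:30, 6:65] <- TRUE
  s3 <- suppressWarnings(identify_soma(as_instance(rect, 1)))  # plateau ties
  expect_equal(s3$diameter_um, 20, tolerance = 0.06)
})

test_that("neurite extraction recovers arm count; bare discs and short arms give none", {
  syn <- gen_neuron(6, list(c(30, 0, 0), c(40, 120, 0), c(35, 240, 0)),
                    pixel_size_um = 0.2)
  cell <- label_instances(syn$mask)[[1L]]
  traces <- extract_neurites(cell)
  expect_length(traces, 3L)
  expect_length(extract_neurites(as_instance(disc_matrix(30), 0.2)), 0L)
  # arm below the length filter is discarded
  syn2 <- gen_neuron(6, list(c(12, 45, 0)), pixel_size_um = 0.2)
  cell2 <- label_instances(syn2$mask)[[1L]]
  expect_length(extract_neurites(cell2, min_neurite_um = 15), 0L)
  expect_length(extract_neurites(cell2, min_neurite_um = 5), 1L)
})

test_that("neurite statistics follow their printed definitions", {
  mk <- function(len) make_trace(cbind(1:2, 1), len)
  st <- neurite_stats(list(mk(10), mk(20), mk(30)))
  expect_equal(st$neurite_count, 3L)
  expect_equal(st$avg_neurite_length_um, 20)
  expect_equal(st$max_neurite_length_um, 30)
  one <- neurite_stats(list(mk(17)))
  expect_equal(one$avg_neurite_length_um, one$max_neurite_length_um)
  none <- neurite_stats(list())
  expect_identical(none$neurite_count, 0L)
  expect_true(is.na(none$avg_neurite_length_um))  # undefined, not zero
})

test_that("straightness is length minus radial distance, zero for straight paths", {
  straight <- make_trace(cbind(1, 1:50), length_um = 49)
  rs <- radial_and_straightness(straight)
  expect_equal(rs$straightness_um, 0)
  # quarter-circle arc of radius r: length pi r / 2, chord r sqrt(2)
  r <- 100
  th <- seq(0, pi / 2, length.out = 400)
  arc <- cbind(1 + r - r * cos(th), 1 + r * sin(th))
  trace <- make_trace(arc, length_um = pi * r / 2)
  rs2 <- radial_and_straightness(trace)
  expect_equal(rs2$radial_distance_um, r * sqrt(2), tolerance = 1e-6)
  expect_equal(rs2$straightness_um, (pi / 2 - sqrt(2)) * r, tolerance = 1e-4)
  expect_gt(rs2$tortuosity, 1)
  # degenerate 2-point trace: radial = length
  two <- make_trace(cbind(c(1, 4), c(1, 5)), length_um = 5)
  expect_equal(radial_and_straightness(two)$straightness_um, 0)
})

test_that("tortuous generated arms have positive straightness", {
  syn <- gen_neuron(6, list(c(30, 20, 1.5)), pixel_size_um = 0.2)
  res <- measure_neuron(label_instances(syn$mask)[[1L]])
  expect_gt(res$traces[[1L]]$straightness_um, 0.5)
})

test_that("chord angles fold into [0, 90] and recover generator angles within 1 degree", {
  ref0 <- list(base = c(row = 10, col = 10), tip = c(row = 10, col = 40))
  expect_equal(alignment_angle(ref0), 0)
  # chord at 100 degrees to the axis folds to 80
  th <- 100 * pi / 180
  t100 <- list(base = c(row = 50, col = 50),
               tip = c(row = 50 - 30 * sin(th), col = 50 + 30 * cos(th)))
  expect_equal(alignment_angle(t100), 80, tolerance = 1e-9)
  for (ang in c(12, 37, 61, 88)) {
    syn <- gen_neuron(6, list(c(30, ang, 0)), pixel_size_um = 0.2)
    res <- measure_neuron(label_instances(syn$mask)[[1L]])
    expect_equal(res$traces[[1L]]$chord_angle_deg, ang, tolerance = 1)
  }
  degen <- list(base = c(row = 1, col = 1), tip = c(row = 1, col = 1))
  expect_error(alignment_angle(degen), class = "semquant_degenerate_error")
})

test_that("alignment classes use strict 15/75 thresholds and partition [0, 90]", {
  expect_identical(classify_alignment(10), "parallel")
  expect_identical(classify_alignment(80), "perpendicular")
  expect_identical(classify_alignment(15), "intermediate")
  expect_identical(classify_alignment(75), "intermediate")
  angles <- seq(0, 90, by = 0.5)
  cls <- classify_alignment(angles)
  expect_true(all(cls %in% c("parallel", "intermediate", "perpendicular")))
  expect_identical(cls, ifelse(angles < 15, "parallel",
                        ifelse(angles > 75, "perpendicular", "intermediate")))
  expect_error(classify_alignment(91), class = "semquant_validation_error")
})

test_that("circularity: analytic disc = 1, analytic square = pi/4, raster disc ~ 1", {
  r <- 3.7
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1, tolerance = 1e-12)
  a <- 2.2
  expect_equal(circularity(a^2, 4 * a), pi / 4, tolerance = 1e-15)
  apc <- area_perimeter_circularity(as_instance(disc_matrix(200), 0.1))
  expect_equal(apc$circularity, 1, tolerance = 0.05)
  expect_equal(apc$area_um2, pi * 20^2, tolerance = 0.01)
})

test_that("isoperimetric bound holds and circularity is rotation/scale invariant", {
  set.seed(7)
  shapes <- list(disc_matrix(30),
                 {m <- matrix(FALSE, 60, 60); m[15:45, 20:40] <- TRUE; m},
                 gen_neuron(5, list(c(15, 30, 0)), pixel_size_um = 0.2)$mask$pixels)
  for (px in shapes) {
    c0 <- area_perimeter_circularity(as_instance(px, 1))$circularity
    expect_lte(c0, 1.05)
    # 90-degree rotation and transposition leave C unchanged (same chain)
    c90 <- area_perimeter_circularity(as_instance(t(px)[ncol(px):1, ], 1))$circularity
    expect_equal(c90, c0, tolerance = 0.02)
    # scale invariance under calibration change
    c2 <- area_perimeter_circularity(as_instance(px, 1), pixel_size_um = 2)$circularity
    expect_equal(c2, c0, tolerance = 1e-12)
  }
})

test_that("perimeter estimator options behave as documented on a large disc", {
  cell <- as_instance(disc_matrix(100), 1)
  p_cal <- area_perimeter_circularity(cell, perimeter_method = "calibrated")
  p_chain <- area_perimeter_circularity(cell, perimeter_method = "chain")
  p_cnt <- area_perimeter_circularity(cell, perimeter_method = "pixel_count")
  expect_equal(p_cal$perimeter_um, 2 * pi * 100, tolerance = 0.01)
  expect_gt(p_chain$perimeter_um, p_cal$perimeter_um)   # naive chain biased high
  expect_lt(p_cnt$perimeter_um, p_cal$perimeter_um)     # pixel count biased low
})

test_that("differentiated cells are those with a neurite at least one soma diameter", {
  df <- data.frame(neurite_count = c(1L, 0L, 2L, 1L),
                   max_neurite_length_um = c(25, NA, 12, 19.9),
                   soma_diameter_um = c(20, 20, 12, 20))
  expect_equal(count_differentiated(df), 2L)  # 25 >= 20 and 12 >= 12
})

test_that("length >= radial distance on every generated fixture", {
  syn <- gen_neuron(6, list(c(25, 10, 0), c(30, 100, 1), c(40, 210, 2)),
                    pixel_size_um = 0.2)
  res <- measure_neuron(label_instances(syn$mask)[[1L]])
  for (t in res$traces)
    expect_gte(t$length_um, t$radial_distance_um)
})
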