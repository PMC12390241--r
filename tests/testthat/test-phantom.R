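test_that("paper-default phantom has nine structures and partial-volume values", {
  ph <- mini_phantom()  # scaled layout, same structure count
  expect_s3_class(ph, "mrm_phantom")
  expect_length(ph$structures, 9)
  expect_true(all(ph$image >= 0 & ph$image <= 1))
  # partial-volume edges exist
  expect_gt(sum(ph$image > 0 & ph$image < 1), 0)
  labs <- vapply(ph$structures, `[[`, "", "label")
  expect_setequal(labs, c(paste0("circle_", c(2, 4, 6, 8, 10, 20, 30, 40)),
                          "square_50"))
})

test_that("integer-aligned square at supersample 1 gives a strictly binary image", {
  sq <- structure_spec("square", 16, c(32, 32))
  ph <- generate_phantom(64, 1, list(sq), roi_side = 8)
  expect_true(all(ph$image %in% c(0, 1)))
  # interior of the structure: exactly 16^2 zero pixels inside the square box
  expect_equal(sum(ph$image[25:40, 25:40] == 0), 256)
  expect_true(all(ph$image[25:40, 25:40] == 0))
})

test_that("intermediate-pixel count matches a brute-force high-res rasterizer", {
  circ <- structure_spec("circle", 20, c(64, 64))
  ph8 <- generate_phantom(128, 8, list(circ), roi_side = 8)
  ph32 <- generate_phantom(128, 32, list(circ), roi_side = 8)
  n8 <- sum(ph8$image > 0 & ph8$image < 1)
  n32 <- sum(ph32$image > 0 & ph32$image < 1)
  expect_lt(abs(n8 - n32) / n32, 0.10)
})

test_that("block averaging conserves the image mean", {
  circ <- structure_spec("circle", 11.5, c(40.3, 33.7))
  n <- 64; s <- 4
  ph <- generate_phantom(n, s, list(circ), roi_side = 8)
  # rebuild the supersampled raster via a supersample-1 phantom at n*s
  big <- generate_phantom(n * s, 1,
                          list(structure_spec("circle", 11.5 * s,
                                              c(40.3 * s, 33.7 * s))),
                          solution = list(shape = "circle", size = 0.7 * n * s,
                                          center = c(n * s / 2, n * s / 2)),
                          roi_side = 8)
  expect_equal(mean(ph$image), mean(big$image), tolerance = 1e-12)
})

test_that("doubling the supersampling factor only moves edge pixels", {
  circ <- structure_spec("circle", 17, c(30.2, 35.8))
  ph8 <- generate_phantom(64, 8, list(circ), roi_side = 8)
  ph16 <- generate_phantom(64, 16, list(circ), roi_side = 8)
  expect_lt(max(abs(ph8$image - ph16$image)), 0.5)
})

test_that("geometry violations are rejected with the offending structure named", {
  too_close <- list(structure_spec("circle", 10, c(30, 30), label = "a"),
                    structure_spec("circle", 10, c(30, 41), label = "b"))
  expect_error(generate_phantom(64, 2, too_close), "a.*b|4-px")
  outside <- list(structure_spec("circle", 10, c(5, 32), label = "edge"))
  expect_error(generate_phantom(64, 2, outside), "edge")
})

test_that("default ROIs cover only pure solution / exterior background", {
  ph <- mini_phantom()
  expect_true(all(roi_pixels(ph$image, ph$signal_roi) == 1))
  expect_true(all(roi_pixels(ph$image, ph$background_roi) == 0))
  # disjoint
  expect_false(any(ph$signal_roi$rows %in% ph$background_roi$rows) &&
                 any(ph$signal_roi$cols %in% ph$background_roi$cols))
  # no placement when the ROI cannot fit in the solution
  expect_error(default_rois(ph, roi_side = ph$n), "placement")
})
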