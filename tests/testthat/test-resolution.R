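test_that("Gaussian blur reference: identity, normalization, brute-force match", {
  ph <- tiny_phantom()
  expect_identical(blur_reference(ph$image, 0), ph$image)
  const <- matrix(0.7, 32, 32)
  expect_lt(max(abs(blur_reference(const, 3) - 0.7)), 1e-12)
  expect_error(blur_reference(const, -1), "non-negative")

  # brute-force 2-D convolution with a wide truncated kernel, replicate edges
  step <- matrix(0, 24, 24); step[, 13:24] <- 1
  sigma <- 2
  r <- 15
  k1 <- exp(-0.5 * (-r:r)^2 / sigma^2); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  pad <- function(m, r) {
    idx <- function(v, n) pmin(pmax(v, 1), n)
    m[idx(seq(1 - r, 24 + r), 24), idx(seq(1 - r, 24 + r), 24)]
  }
  sp <- pad(step, r)
  brute <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24)
    brute[i, j] <- sum(k2 * sp[i:(i + 2 * r), j:(j + 2 * r)])
  expect_lt(max(abs(blur_reference(step, sigma) - brute)), 1e-6)
})

test_that("blur fitting recovers known sigmas within 2%", {
  ph <- mini_phantom()
  win <- structure_window(ph, "circle_20")
  for (s0 in c(0.5, 1, 2, 4)) {
    blurred <- blur_reference(ph$image, s0)
    est <- fit_blur_sigma(blurred, ph$image, win)
    expect_lt(abs(est$sigma - s0) / s0, 0.02)
    expect_equal(est$beta, 2 * est$sigma)
  }
  # recon == ideal pins sigma at the lower search bound
  est0 <- fit_blur_sigma(ph$image, ph$image, win)
  expect_lte(est0$sigma, 0.0101)
  expect_true(est0$boundary)
  # self-consistency at sigma = 2 to +-0.02 absolute
  est2 <- fit_blur_sigma(blur_reference(ph$image, 2), ph$image, win)
  expect_lt(abs(est2$sigma - 2), 0.02)
})

test_that("SSE is unimodal in sigma on recovery instances", {
  ph <- tiny_phantom()
  win <- structure_window(ph, "circle_20")
  blurred <- blur_reference(ph$image, 1.5)
  sses <- vapply(seq(0.2, 6, by = 0.2), function(s)
    sum((roi_pixels(blurred, win) -
           roi_pixels(blur_reference(ph$image, s), win))^2), numeric(1))
  drops <- diff(sses) < 0
  # decreasing then increasing: exactly one sign change in the differences
  expect_equal(sum(diff(drops) != 0), 1)
})

test_that("upsampled-grid fits convert with the sigma' = sigma/factor rule", {
  expect_equal(resolution_from_upsampled(20.5, 2), 20.5)
  expect_equal(resolution_from_upsampled(37.7, 2), 37.7)
  expect_equal(resolution_from_upsampled(0, 2), 0)
  expect_equal(resolution_from_upsampled(3, 2, pixel_size = 30), 90)
  # fitting on a 2x bilinear upsample halves the effective sigma
  ph <- mini_phantom()
  blurred <- blur_reference(ph$image, 1.2)
  up <- upsample_bilinear(blurred, 2)
  ideal_up <- upsample_bilinear(ph$image, 2)
  w <- structure_window(ph, "circle_20")
  wu <- roi((2 * min(w$rows)):(2 * max(w$rows)),
            (2 * min(w$cols)):(2 * max(w$cols)))
  est <- fit_blur_sigma(up, ideal_up, wu, upsample_factor = 2)
  expect_lt(abs(est$beta - 2 * 1.2), 0.25)
})

test_that("line profiles: constants, exact rows, and circle width", {
  const <- matrix(0.3, 20, 20)
  expect_equal(extract_line_profile(const, c(3, 2), c(18, 17), 25),
               rep(0.3, 25))
  img <- matrix(seq_len(400) %% 7, 20, 20) * 1.0
  expect_equal(extract_line_profile(img, c(5, 1), c(5, 20), 20), img[5, ])
  expect_error(extract_line_profile(const, c(0, 3), c(5, 5), 10), "outside")

  # full width at half depth of a 10-px circle (value 0 in solution 1)
  circ <- structure_spec("circle", 10, c(32, 32))
  ph <- generate_phantom(64, 8, list(circ), roi_side = 8)
  prof <- extract_line_profile(ph$image, c(32.5, 20.5), c(32.5, 44.5), 481)
  xs <- seq(20.5, 44.5, length.out = 481)
  below <- xs[prof < 0.5]
  expect_lt(abs((max(below) - min(below)) - 10), 1)
})
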