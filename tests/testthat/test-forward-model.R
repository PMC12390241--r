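test_that("centered unitary DFT: DC placement, inversion, Parseval", {
  K <- image_to_kspace(matrix(1, 8, 8))
  expect_equal(Mod(K[5, 5]), 8, tolerance = 1e-12)  # DC = N * mean at center
  expect_lt(max(Mod(K[-(5 + 8 * 4)])), 1e-12)
  # impulse at the center index inverts to a constant image
  imp <- matrix(0 + 0i, 8, 8); imp[5, 5] <- 8
  expect_lt(max(Mod(kspace_to_image(imp) - 1)), 1e-12)
  expect_true(all(kspace_to_image(matrix(0 + 0i, 8, 8)) == 0))

  z <- random_cx(16, seed = 2)
  expect_lt(max(Mod(kspace_to_image(image_to_kspace(z)) - z)), 1e-10)
  expect_lt(abs(sum(Mod(z)^2) - sum(Mod(image_to_kspace(z))^2)), 1e-10)
  expect_error(image_to_kspace(matrix(0, 4, 8)), "square")
})

test_that("Rayleigh-corrected SNR formula and degenerate input", {
  img <- matrix(0, 32, 32)
  sig <- roi(1:8, 1:8); bg <- roi(20:27, 20:27)
  img[sig$rows, sig$cols] <- 1
  # background with sd exactly sqrt(2 - pi/2) => SNR = 1
  s <- sqrt(2 - pi / 2)
  img[bg$rows, bg$cols] <- rep(c(-s, s), 32) * sqrt(63 / 64)  # sample sd = s
  expect_equal(measure_snr(img, sig, bg), 1, tolerance = 1e-12)
  expect_error(measure_snr(matrix(1, 16, 16), roi(1:4, 1:4), roi(9:12, 9:12)),
               "standard deviation")
})

test_that("noise calibration hits the target SNR on average", {
  ph <- mini_phantom()
  k0 <- image_to_kspace(ph$image)
  full <- matrix(TRUE, ph$n, ph$n)
  # sigma has the closed form S/target
  kn <- add_noise_for_target_snr(k0, 20, ph, seed = 1)
  expect_equal(kn$noise_sigma, 0.05)
  # "infinite" adds no noise, bit-identical
  expect_identical(add_noise_for_target_snr(k0, "infinite", ph)$data, k0)
  expect_error(add_noise_for_target_snr(k0, -3, ph), "positive")
  # Monte-Carlo: mean measured SNR within 5% of target over 100 seeds
  v15 <- vapply(1:100, function(s) {
    kn <- add_noise_for_target_snr(k0, 15, ph, seed = s)
    measure_snr(Mod(kspace_to_image(kn$data)), ph$signal_roi,
                ph$background_roi)
  }, numeric(1))
  expect_lt(abs(mean(v15) - 15) / 15, 0.05)
  # every nominal level of the study grid within 10% (20 seeds each)
  for (lev in c(4, 10, 30, 100)) {
    v <- vapply(1:20, function(s) {
      kn <- add_noise_for_target_snr(k0, lev, ph, seed = 1000 + s)
      measure_snr(Mod(kspace_to_image(kn$data)), ph$signal_roi,
                  ph$background_roi)
    }, numeric(1))
    expect_lt(abs(mean(v) - lev) / lev, 0.10)
  }
})

test_that("same seed gives bit-identical noisy k-space", {
  ph <- tiny_phantom()
  k0 <- image_to_kspace(ph$image)
  a <- add_noise_for_target_snr(k0, 10, ph, seed = 42)
  b <- add_noise_for_target_snr(k0, 10, ph, seed = 42)
  expect_identical(a$data, b$data)
  c <- add_noise_for_target_snr(k0, 10, ph, seed = 43)
  expect_false(identical(a$data, c$data))
})
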