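test_that("wavelet transform is orthonormal with perfect reconstruction", {
  x <- withr::with_seed(4, matrix(rnorm(64^2), 64))
  w <- dwt2(x, 4)
  expect_lt(max(abs(idwt2(w, 4) - x)), 1e-12)
  expect_lt(abs(sum(w^2) - sum(x^2)) / sum(x^2), 1e-12)
  expect_error(dwt2(matrix(0, 24, 24), 4), "divisible")
})

test_that("zero-filled reconstruction contracts", {
  ph <- tiny_phantom()
  kn <- noisy_kspace(ph, 20, seed = 3)
  full <- matrix(TRUE, 64, 64)
  zf <- zero_fill_recon(kn, full)
  expect_lt(max(Mod(zf$image - kspace_to_image(kn$data))), 1e-10)
  expect_equal(zf$magnitude, Mod(zf$image))
  expect_true(all(zero_fill_recon(matrix(0 + 0i, 64, 64), full)$image == 0))
  # undersampling strictly degrades the noise-free phantom
  k0 <- image_to_kspace(ph$image)
  mk <- make_sampling_mask(64, 4, 2, center_radius = mini_radius(64), seed = 5)
  e_us <- nrmse(zero_fill_recon(k0, mk)$magnitude, ph$image)
  e_full <- nrmse(zero_fill_recon(k0, full)$magnitude, ph$image)
  expect_gt(e_us, e_full)
})

test_that("unregularized CS on a full mask equals the inverse transform", {
  y <- image_to_kspace(matrix(withr::with_seed(8, rnorm(256)), 16))
  r <- cs_l1wavelet_recon(y, matrix(TRUE, 16, 16), lam = 0, max_iters = 500,
                          tol = 1e-12)
  expect_lt(max(Mod(r$image - kspace_to_image(y))), 1e-6)
})

test_that("CS objective is monotone and the iterate near-optimal on toys", {
  # independent oracle: plain ISTA (no momentum) run far past convergence,
  # from helper-oracles.R
  img <- tiny_phantom()$image[25:40, 25:40]  # contains the central structure
  y <- image_to_kspace(img)
  m <- withr::with_seed(11, matrix(runif(256) < 0.6, 16, 16))
  m[8:10, 8:10] <- TRUE
  lam <- 5e-3
  y <- y + withr::with_seed(12, matrix(complex(real = rnorm(256, sd = 0.01),
                                               imaginary = rnorm(256, sd = 0.01)),
                                       16, 16))
  fit <- cs_l1wavelet_recon(y, m, lam = lam, max_iters = 2000, tol = 1e-12)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))

  sc <- fit$params$scale
  obj_fit <- fit$objective_trace[length(fit$objective_trace)]
  # oracle runs from three different initializations on the normalized data
  starts <- list(matrix(0 + 0i, 16, 16),
                 kspace_to_image(y * m) / sc,
                 matrix(complex(real = withr::with_seed(13, rnorm(256, sd = .1)),
                                imaginary = 0), 16, 16))
  for (x0 in starts) {
    xo <- ista_oracle(x0, y * m / sc, m, lam)
    obj_o <- toy_objective(xo, y * m / sc, m, lam)
    expect_lt(abs(obj_fit - obj_o) / obj_o, 1e-6)
  }
})

test_that("CS solution satisfies the subgradient optimality conditions", {
  img <- tiny_phantom()$image[17:48, 17:48]  # 32 x 32 crop
  y <- image_to_kspace(img)
  m <- withr::with_seed(21, matrix(runif(32^2) < 0.5, 32, 32))
  m[15:18, 15:18] <- TRUE
  lam <- 2e-3
  fit <- cs_l1wavelet_recon(y, m, lam = lam, max_iters = 3000, tol = 1e-13)
  sc <- fit$params$scale
  x <- fit$image / sc
  # gradient of the data term mapped to the wavelet domain
  g <- kspace_to_image((image_to_kspace(x) - y * m / sc) * m)
  gw <- complex(real = dwt2(Re(g), 4), imaginary = dwt2(Im(g), 4))
  w <- complex(real = dwt2(Re(x), 4), imaginary = dwt2(Im(x), 4))
  on_sup <- Mod(w) > 1e-9
  # on the support: gradient + lam * sign(w) = 0; off: |gradient| <= lam
  expect_lt(max(Mod(gw[on_sup] + lam * w[on_sup] / Mod(w[on_sup]))), 1e-4)
  expect_lt(max(Mod(gw[!on_sup])), lam + 1e-4)
})

test_that("large lam drives wavelet coefficients outside the data span to zero", {
  ph <- tiny_phantom()
  k0 <- image_to_kspace(ph$image)
  mk <- make_sampling_mask(64, 4, 2, center_radius = mini_radius(64), seed = 9)
  big <- cs_l1wavelet_recon(k0, mk, lam = 10, max_iters = 300)
  w <- dwt2(Re(big$image / big$params$scale), 4)
  # with lam far above the data scale nearly everything is thresholded away
  expect_gt(mean(abs(w) < 1e-8), 0.5)
  small <- cs_l1wavelet_recon(k0, mk, lam = 2e-3, max_iters = 100)
  ws <- dwt2(Re(small$image / small$params$scale), 4)
  expect_gt(sum(abs(w) < 1e-8), sum(abs(ws) < 1e-8))
})

test_that("CS beats zero-filling on the undersampled noisy phantom", {
  ph <- mini_phantom()
  kn <- noisy_kspace(ph, 15, seed = 31)
  mk <- make_sampling_mask(128, 4, 2, center_radius = mini_radius(128),
                           seed = 31)
  e_cs <- nrmse(cs_l1wavelet_recon(kn, mk)$magnitude, ph$image)
  e_zf <- nrmse(zero_fill_recon(kn, mk)$magnitude, ph$image)
  expect_lt(e_cs, e_zf)
})
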