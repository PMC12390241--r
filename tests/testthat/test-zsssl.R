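test_that("k-space partition is disjoint, exhaustive and seeded", {
  mk <- make_sampling_mask(128, 4, 2, center_radius = 15, seed = 2)
  for (s in 1:5) {
    sp <- split_measurements(mk, 0.2, 0.4, seed = s)
    expect_false(any(sp$theta & sp$lam))
    expect_false(any(sp$theta & sp$gamma))
    expect_false(any(sp$lam & sp$gamma))
    expect_identical(sp$theta | sp$lam | sp$gamma, mk$mask)
    expect_true(all(vapply(sp[c("theta", "lam", "gamma")], sum, 0) > 0))
  }
  # gamma count is exact
  sp <- split_measurements(mk, 0.2, 0.4, seed = 1)
  expect_equal(sum(sp$gamma), round(0.2 * sum(mk$mask)))
  # calibration disk lives in theta
  ic <- 65
  d2 <- outer((seq_len(128) - ic)^2, (seq_len(128) - ic)^2, `+`)
  expect_true(all(sp$theta[d2 <= 15^2 & mk$mask]))
  # pathological fraction leaves a subset empty
  expect_error(split_measurements(mk, 0.999, 0.4, seed = 1), "empty")
  expect_identical(split_measurements(mk, 0.2, 0.4, seed = 3)$theta,
                   split_measurements(mk, 0.2, 0.4, seed = 3)$theta)
})

test_that("dc_solve matches the single-coil diagonal closed form", {
  for (s in 1:20) {
    n <- 32
    z <- random_cx(n, seed = s)
    y <- random_cx(n, seed = 100 + s)
    m <- withr::with_seed(200 + s, matrix(runif(n^2) < 0.4, n, n))
    mu <- withr::with_seed(300 + s, runif(1, 0.01, 2))
    x <- dc_solve(z, y, m, mu, cg_iters = 10)
    K <- image_to_kspace(z)
    K[m] <- (y[m] + mu * K[m]) / (1 + mu)
    xo <- kspace_to_image(K)
    expect_lt(max(Mod(x - xo)) / max(Mod(xo)), 1e-6)
  }
  # limits: full mask mu=0 inverts; huge mu returns the prior
  z <- random_cx(16, seed = 5); y <- random_cx(16, seed = 6)
  full <- matrix(TRUE, 16, 16)
  expect_lt(max(Mod(dc_solve(z, y, full, 0) - kspace_to_image(y))), 1e-8)
  expect_lt(max(Mod(dc_solve(z, y, full, 1e8) - z)) / max(Mod(z)), 1e-6)
})

test_that("mixed-norm loss values and scale invariance", {
  u <- c(1 + 2i, -3, 0.5i)
  expect_equal(mixed_norm_loss(u, u), 0)
  expect_equal(mixed_norm_loss(u, u * 0), 2)
  expect_equal(mixed_norm_loss(c(1, 0), c(0, 1)), 2 + sqrt(2),
               tolerance = 1e-12)
  v <- c(2 - 1i, 1, 3i)
  for (cc in c(2, -0.3, 1i)) {
    expect_equal(mixed_norm_loss(cc * u, cc * v), mixed_norm_loss(u, v),
                 tolerance = 1e-12)
  }
  expect_error(mixed_norm_loss(c(0, 0), c(1, 1)), "zero")
})

test_that("unrolled forward with zero conv weights is repeated data consistency", {
  cfg <- test_zs_config(unrolls = 3)
  p <- mrmbench:::zs_init_params(cfg)
  p$W_in <- p$W_in * 0
  for (b in seq_along(p$W1)) { p$W1[[b]] <- p$W1[[b]] * 0; p$W2[[b]] <- p$W2[[b]] * 0 }
  ph <- tiny_phantom()
  k <- image_to_kspace(ph$image)
  mk <- make_sampling_mask(64, 2, 2, center_radius = 8, seed = 4)
  out <- unrolled_forward(k, mk, p, cfg)
  x <- kspace_to_image(k * mk$mask)
  for (i in 1:3) x <- dc_solve(x, k * mk$mask, mk$mask, p$mu)
  expect_lt(max(Mod(out - x)), 1e-10)
  expect_identical(dim(out), dim(k))
})

test_that("training improves validation loss and is deterministic", {
  ph <- tiny_phantom()
  kn <- noisy_kspace(ph, 20, seed = 5)
  mk <- make_sampling_mask(64, 2, 2, center_radius = mini_radius(64), seed = 5)
  cfg <- test_zs_config(max_epochs = 40, patience = 40, seed = 7)
  fit <- train_zs_ssl(kn, mk, cfg)
  expect_equal(nrow(fit$history), fit$stop_epoch)
  expect_lte(fit$stop_epoch, cfg$max_epochs)
  expect_lt(fit$history$val[nrow(fit$history)], fit$history$val[1])
  fit2 <- train_zs_ssl(kn, mk, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("the literal early-stopping rule is available", {
  ph <- tiny_phantom()
  kn <- noisy_kspace(ph, 20, seed = 6)
  mk <- make_sampling_mask(64, 2, 2, center_radius = mini_radius(64), seed = 6)
  cfg <- test_zs_config(max_epochs = 30, patience = 3,
                        early_stopping = "literal", seed = 2)
  fit <- train_zs_ssl(kn, mk, cfg)
  expect_true(fit$stop_reason %in% c("literal_rule", "max_epochs"))
  if (fit$stop_reason == "literal_rule") {
    h <- fit$history
    k <- nrow(h)
    expect_true(all(h$train[(k - 2):k] > h$val[(k - 2):k]))
  }
})

test_that("final reconstruction uses all measurements and honors contracts", {
  ph <- tiny_phantom()
  mk <- make_sampling_mask(64, 1, 2, center_radius = mini_radius(64), seed = 8)
  kn <- noisy_kspace(ph, 50, seed = 8)
  cfg <- test_zs_config(max_epochs = 30, patience = 30, seed = 3)
  fit <- train_zs_ssl(kn, mk, cfg)
  rec <- zs_ssl_reconstruct(kn, mk, fit)
  expect_equal(rec$magnitude, Mod(rec$image))
  # fully sampled: near-identity with the direct inverse transform
  expect_lt(nrmse(rec$magnitude, Mod(kspace_to_image(kn$data))), 0.05)
  # mask mismatch is a contract error
  other <- make_sampling_mask(64, 2, 2, center_radius = mini_radius(64),
                              seed = 9)
  expect_error(zs_ssl_reconstruct(kn, other, fit), "mask")
})

test_that("ZS-SSL beats zero-filling on the undersampled noisy phantom", {
  ph <- mini_phantom()
  kn <- noisy_kspace(ph, 15, seed = 12)
  mk <- make_sampling_mask(128, 4, 2, center_radius = mini_radius(128),
                           seed = 12)
  cfg <- test_zs_config(max_epochs = 60, patience = 20, seed = 4)
  rec <- zs_ssl_recon(kn, mk, cfg)
  e_zs <- nrmse(rec$magnitude, ph$image)
  e_zf <- nrmse(zero_fill_recon(kn, mk)$magnitude, ph$image)
  expect_lt(e_zs, e_zf)
})
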