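test_that("mask budget is exact and the calibration disk fully sampled", {
  for (af in c(2, 4, 8)) for (pat in 1:3) {
    mk <- make_sampling_mask(128, af, pat, center_radius = 15,
                             seed = af * 10 + pat)
    expect_equal(sum(mk$mask), round(128^2 / af))
    ic <- 65
    d <- sqrt(outer((seq_len(128) - ic)^2, (seq_len(128) - ic)^2, `+`))
    expect_true(all(mk$mask[d <= 15]))
  }
  # af = 1: everything acquired
  expect_true(all(make_sampling_mask(64, 1, 2)$mask))
  expect_equal(achieved_af(make_sampling_mask(64, 1, 2)), 1.0)
})

test_that("achieved AF matches construction and errors on empty masks", {
  mk <- make_sampling_mask(256, 4, 2, seed = 1)
  expect_equal(achieved_af(mk), 256^2 / round(256^2 / 4))
  mk8 <- make_sampling_mask(256, 8, 1, seed = 2)
  expect_lt(abs(achieved_af(mk8) - 8), 8 * 2 / 256^2 * 8)  # one-sample rounding
  expect_error(achieved_af(matrix(FALSE, 4, 4)), "empty")
})

test_that("infeasible AF reports the maximum feasible value", {
  expect_error(make_sampling_mask(64, 60, 2, center_radius = 15),
               "max feasible AF")
})

test_that("masks are deterministic given the seed", {
  a <- make_sampling_mask(128, 4, 2, seed = 7)
  b <- make_sampling_mask(128, 4, 2, seed = 7)
  c <- make_sampling_mask(128, 4, 2, seed = 8)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$mask, c$mask))
})

test_that("pattern 2 concentrates more samples near the center than pattern 3", {
  n <- 256
  ic <- n / 2 + 1
  d <- sqrt(outer((seq_len(n) - ic)^2, (seq_len(n) - ic)^2, `+`))
  annulus <- d > 30 & d <= 60
  frac <- function(pat, seed) {
    mk <- make_sampling_mask(n, 4, pat, center_radius = 30, seed = seed)
    mean(mk$mask[annulus])
  }
  f2 <- vapply(1:50, function(s) frac(2, s), numeric(1))
  f3 <- vapply(1:50, function(s) frac(3, s), numeric(1))
  expect_gt(mean(f2), mean(f3))
})

test_that("pattern 1 outside-disk samples are radially uniform", {
  # chi-square on radial-bin counts pooled over 200 seeds, alpha = 0.01
  n <- 128
  ic <- n / 2 + 1
  d <- sqrt(outer((seq_len(n) - ic)^2, (seq_len(n) - ic)^2, `+`))
  outside <- d > 15
  bins <- cut(d[outside], breaks = c(15, 25, 35, 45, 55, Inf))
  avail <- table(bins)
  counts <- rep(0, length(avail))
  for (s in 1:200) {
    mk <- make_sampling_mask(n, 4, 1, center_radius = 15, seed = 3000 + s)
    sampled <- mk$mask[outside]
    counts <- counts + tapply(sampled, bins, sum)
  }
  p_uniform <- avail / sum(avail)
  test <- suppressWarnings(chisq.test(counts, p = as.vector(p_uniform)))
  expect_gt(test$p.value, 0.01)
})
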