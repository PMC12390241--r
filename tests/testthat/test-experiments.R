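# Grid orchestration: counting, determinism, resume. Small grids only; the
# scientific content of the full protocol lives in test-acceptance.R.

mini_config <- function(output_dir = NULL, ...) {
  experiment_config(n = 64, methods = "zero_fill", afs = 2,
                    snr_levels = c(10, 30), patterns = 2, n_trials = 2,
                    base_seed = 5, supersample = 4, output_dir = output_dir,
                    ...)
}

test_that("run_condition records a full trial and is deterministic", {
  cfg <- mini_config()
  ph <- generate_phantom(64, 4)
  a <- run_condition(cfg, "zero_fill", 2, 10, 2, 1, phantom = ph)
  b <- run_condition(cfg, "zero_fill", 2, 10, 2, 1, phantom = ph)
  expect_equal(a$beta, b$beta)
  expect_equal(a$seed, b$seed)
  expect_true(a$beta >= 0)
  # different cells get different seeds
  c2 <- run_condition(cfg, "zero_fill", 2, 10, 2, 2, phantom = ph)
  expect_false(a$seed == c2$seed)
  # noise-free fully sampled: beta collapses to the fit floor
  inf <- run_condition(cfg, "zero_fill", 1, "infinite", 2, 1, phantom = ph)
  expect_lt(inf$beta, 0.05)
})

test_that("run_grid covers the grid and aggregates one curve per cell group", {
  cfg <- mini_config()
  res <- run_grid(cfg)
  expect_equal(nrow(res$records), 2 * 2)  # 2 SNRs x 2 trials
  expect_length(res$curves, 1)
  expect_s3_class(res$curves[[1]], "snrl_curve")
  expect_equal(res$curves[[1]]$n_trials, 2)
  expect_equal(nrow(res$summary), 1)
})

test_that("run_grid resumes from on-disk records", {
  dir <- tempfile("gridcache")
  cfg <- mini_config(output_dir = dir)
  res1 <- run_grid(cfg)
  files <- list.files(dir, pattern = "^cell_")
  expect_length(files, 4)
  # tamper with one cached cell: resume must keep it, not recompute
  f <- file.path(dir, files[1])
  rec <- read.csv(f)
  rec$beta <- 123
  write.csv(rec, f, row.names = FALSE)
  res2 <- run_grid(cfg)
  expect_true(any(res2$records$beta == 123))
  # deleting the record forces recomputation of exactly that cell
  file.remove(f)
  res3 <- run_grid(cfg)
  expect_false(any(res3$records$beta == 123))
  expect_equal(sort(res3$records$beta), sort(res1$records$beta))
  unlink(dir, recursive = TRUE)
})

test_that("compare_patterns returns one curve per pattern and the argmin", {
  cfg <- experiment_config(n = 64, methods = "cs_l1w", afs = 4,
                           snr_levels = c(8, 30), patterns = c(1, 2),
                           n_trials = 1, base_seed = 2, supersample = 4)
  out <- compare_patterns(cfg, af = 4)
  expect_length(out$curves, 2)
  expect_true(out$best_pattern %in% c(1, 2))
  expect_error(compare_patterns(mini_config(), af = 2), "single")
})
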