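# Shared benchmark protocols for the acceptance-style tests. Expensive grids
# are computed once per test run and cached in fixture_cache.
#
# Two problem scales are used:
#  * the reference protocol at N = 512 (the study geometry; trials reduced
#    from 10 to 3 where noted to keep the default run affordable), and
#  * a miniature protocol at N = 128 in which every length — phantom layout
#    and the 30-px calibration disk — scales by 128/512, so the sampling
#    geometry in normalized k-space units matches the reference exactly.

accept_seed <- 101L

phantom512 <- function() fixture("phantom512", function() {
  generate_phantom(512, 8)
})

# reduced-architecture scan-specific network for the miniature protocol;
# the epoch cap is high enough that validation-based early stopping, not the
# cap, normally ends training
mini_zs_cfg <- function() {
  zs_ssl_config(unrolls = 5, residual_blocks = 2, filters = 8,
                max_epochs = 200, patience = 20)
}

# CS rows of the summary table at the reference scale, 3 trials
cs512_grid <- function() fixture("cs512_grid", function() {
  cfg <- experiment_config(n = 512, methods = "cs_l1w", afs = c(2, 4),
                           patterns = 2, n_trials = 3, base_seed = accept_seed)
  run_grid(cfg, phantom = phantom512())
})

# fully sampled behavior at the reference scale, 10 trials
fs512_grid <- function() fixture("fs512_grid", function() {
  cfg <- experiment_config(n = 512, methods = "zero_fill", afs = 1,
                           patterns = 2, n_trials = 10,
                           base_seed = accept_seed)
  run_grid(cfg, phantom = phantom512())
})

# miniature-protocol grids; the coarse SNR grids subsample the nine-level
# study grid around the expected beta = 1 crossings
mini_grid <- function(methods, afs, snrs, n_trials, key) {
  fixture(key, function() {
    cfg <- experiment_config(n = 128, methods = methods, afs = afs,
                             snr_levels = snrs, patterns = 2,
                             n_trials = n_trials, base_seed = accept_seed,
                             zs = mini_zs_cfg())
    run_grid(cfg, phantom = mini_phantom())
  })
}

mini_zs_af2 <- function() mini_grid("zs_ssl", 2, c(4, 6, 10, 15), 3,
                                    "mini_zs_af2")
mini_zs_af4 <- function() mini_grid("zs_ssl", 4, c(6, 15, 30), 3,
                                    "mini_zs_af4")
mini_cs_af2 <- function() mini_grid(c("zero_fill", "cs_l1w"), 2,
                                    c(4, 6, 10, 15, 30), 3, "mini_cs_af2")
# (the CS grid keeps SNR 30 so its own beta = 1 crossing stays bracketed)
mini_cs_af4 <- function() mini_grid(c("zero_fill", "cs_l1w"), 4,
                                    c(6, 15, 30), 3, "mini_cs_af4")

# SNR_L of a curve mapped to an extended line for ordering comparisons:
# curves that stay below threshold map to -Inf, curves that never reach it
# to +Inf
snrl_ordered <- function(curve) {
  switch(curve$status, le_min = -Inf, na = Inf, curve$snr_l)
}
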