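# Shared fixtures: small phantoms and reconstruction problems built in code.
# Cached per test run since they are deterministic.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# 128-px miniature of the reference phantom (geometry scaled by 128/512)
mini_phantom <- function() fixture("mini_phantom", function() {
  generate_phantom(128, 8)
})

# 64-px phantom for the cheapest end-to-end checks
tiny_phantom <- function() fixture("tiny_phantom", function() {
  generate_phantom(64, 4)
})

# miniature protocol calibration-disk radius: 30 px scaled by n/512
mini_radius <- function(n) 30 * n / 512

# noisy k-space for a phantom at a target SNR
noisy_kspace <- function(ph, snr, seed) {
  add_noise_for_target_snr(image_to_kspace(ph$image), snr, ph, seed = seed)
}

# small ZS-SSL configuration used throughout the tests (reduced architecture;
# the package default is the full 10-unroll, 5-block, 64-filter network)
test_zs_config <- function(...) {
  args <- utils::modifyList(list(unrolls = 5, residual_blocks = 2,
                                 filters = 8, max_epochs = 100, patience = 20,
                                 seed = 1), list(...))
  do.call(zs_ssl_config, args)
}

random_cx <- function(n, seed = 1) {
  withr::with_seed(seed, matrix(complex(real = rnorm(n * n),
                                        imaginary = rnorm(n * n)), n, n))
}
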