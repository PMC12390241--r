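# mrmbench

Benchmarking the *effective* spatial resolution of undersampled MR microscopy
(MRM) reconstruction.

## The problem

MRM acquisitions at tens-of-micrometer voxels take hours; undersampling
k-space by an acceleration factor AF cuts scan time proportionally, but the
reconstruction — not the protocol — decides how much resolution survives.
`mrmbench` is a simulation framework for people designing accelerated MRM
protocols who need to answer: *at this AF and this SNR, with this
reconstruction, is the nominal voxel size still real?*

It provides, end to end:

* a partial-volume **numerical phantom** (solution at intensity 1 with nine
  embedded signal-free structures, block-averaged from an 8x supersampled
  raster);
* a unitary centered Fourier **forward model** with calibrated complex
  Gaussian k-space noise and Rayleigh-corrected SNR measurement,
  `SNR = sqrt(2 - pi/2) * S_target / sd(background)`;
* variable-density Cartesian **sampling masks** with a fully sampled central
  calibration disk and an exact budget `round(N^2/AF)`;
* three reconstructions: **zero-filling**, **L1-wavelet compressed sensing**
  (`argmin 0.5||M(Fx - y)||^2 + lambda||Psi x||_1`, monotone FISTA,
  Daubechies-4, lambda = 2e-3), and **ZS-SSL** — a scan-specific zero-shot
  self-supervised unrolled network (MoDL-style alternation of a ResNet
  denoiser and closed-form data consistency, trained on a three-way partition
  Theta/Lambda/Gamma of the acquired k-space with mixed L1/L2 losses and
  validation-based early stopping);
* a blur-fitting **resolution estimator**: the sigma minimizing
  `SSE(recon, W * G(sigma))` over a structure window, reported as
  `beta = 2*sigma` pixels (Sparrow-criterion convention);
* the **SNR_L** statistic: the lowest SNR at which `beta <= 1 px`, linearly
  interpolated from the beta-versus-SNR curve over seeded trials, tabulated
  per method x AF.

The compute-heavy cores (FFT via FFTW, the wavelet transform, the FISTA
loop, and the unrolled network with hand-derived reverse-mode gradients) are
in C++ (Rcpp/RcppArmadillo).

## A worked example

```r
library(mrmbench)

ph <- generate_phantom(128, 8)          # 128-px miniature of the 512-px phantom
k  <- image_to_kspace(ph$image)
kn <- add_noise_for_target_snr(k, 15, ph, seed = 1)
mk <- make_sampling_mask(128, af = 2, pattern = 2, center_radius = 7.5, seed = 1)

zf <- zero_fill_recon(kn, mk)
cs <- cs_l1wavelet_recon(kn, mk)
zs <- zs_ssl_recon(kn, mk, zs_ssl_config(unrolls = 5, residual_blocks = 2,
                                         filters = 8, max_epochs = 120))

win <- structure_window(ph, "circle_20")
sapply(list(zero_fill = zf, cs_l1w = cs, zs_ssl = zs), function(r)
  fit_blur_sigma(r$magnitude, ph$image, win, signal_roi = ph$signal_roi)$beta)
#> zero_fill    cs_l1w    zs_ssl
#> 3.2962194 1.0448564 0.9023206
```

Read: at AF = 2 and SNR 15 on this miniature protocol, zero-filling delivers
~3.3 px of effective resolution (blurred across three voxels), conventional
CS ~1.04 px, and the scan-specific network ~0.90 px — only the network
preserves the nominal 1-px resolution at this SNR. Aggregating such numbers
over trials and SNR levels gives the summary table:

```r
cfg <- experiment_config(n = 128, methods = "cs_l1w", afs = 2,
                         snr_levels = c(4, 6, 10, 15, 30), n_trials = 3,
                         base_seed = 101)
res <- run_grid(cfg)
res$summary
#>   method af pattern    snr_l status
#> 1 cs_l1w  2       2 25.27933     ok
```

`compare_patterns()` does the same across the three sampling densities, and
`inst/cli/mrmbench.R` wraps grid runs and single reconstructions for shell
use with YAML configs and NIfTI/CSV input-output.

The methods vignette (`vignettes/resolution-benchmarking.Rmd`) documents the
model, every tunable with units and defaults, the design decisions behind
the estimator and the network, and what the miniature test protocol does and
does not preserve of the full-scale study.

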