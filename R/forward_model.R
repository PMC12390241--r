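# Forward model: centered unitary 2-D DFT, calibrated complex Gaussian
# k-space noise, and Rayleigh-corrected SNR measurement on magnitude images.

#' Image to centered k-space
#'
#' Unitary centered 2-D discrete Fourier transform. The DC component sits at
#' 0-based index `(N/2, N/2)` (1-based `N/2 + 1`) for even `N`, and Parseval's
#' identity holds exactly: `sum(|image|^2) = sum(|kspace|^2)`.
#'
#' @param image real or complex square matrix.
#' @return complex matrix of the same size.
#' @export
image_to_kspace <- function(image) {
  check_square(image, "image")
  cpp_fft2c(as_complex_matrix(image))
}

#' Centered k-space to image
#'
#' Inverse of [image_to_kspace()] (unitary, so also norm-preserving).
#'
#' @param kspace complex square matrix with DC at the center index.
#' @return complex image matrix.
#' @export
kspace_to_image <- function(kspace) {
  check_square(kspace, "kspace")
  cpp_ifft2c(as_complex_matrix(kspace))
}

#' Rayleigh-corrected SNR of a magnitude image
#'
#' `SNR = sqrt(2 - pi/2) * mean(signal ROI) / sd(background ROI)`. The factor
#' `sqrt(2 - pi/2)` corrects the background standard deviation for the
#' Rayleigh distribution that magnitude images follow in signal-free regions,
#' so the result estimates signal over the per-channel Gaussian noise sigma.
#'
#' @param magnitude_image real matrix (take `Mod()` of complex
#'   reconstructions first).
#' @param signal_roi,background_roi [roi()] regions.
#' @return a single number.
#' @export
measure_snr <- function(magnitude_image, signal_roi, background_roi) {
  if (is.complex(magnitude_image))
    stop("measure_snr expects a magnitude image; take Mod() first")
  s <- mean(roi_pixels(magnitude_image, signal_roi))
  sb <- sd(as.vector(roi_pixels(magnitude_image, background_roi)))
  if (sb == 0)
    stop("background ROI has zero standard deviation (noise-free image?)")
  sqrt(2 - pi / 2) * s / sb
}

#' Add complex Gaussian k-space noise for a target image SNR
#'
#' Adds i.i.d. complex Gaussian noise with per-channel standard deviation
#' `sigma_k = S_target / target_snr` to every k-space sample, where `S_target`
#' is the phantom's solution intensity (the mean of the ideal image over the
#' signal ROI). Under the unitary transform the image-domain channel sigma
#' equals the k-space sigma, so the measured Rayleigh-corrected SNR matches
#' the target in expectation.
#'
#' @param kspace complex square matrix (e.g. from [image_to_kspace()]).
#' @param target_snr positive number, or `"infinite"` / `Inf` for no noise.
#' @param phantom the source [generate_phantom()] object (supplies the signal
#'   level and the ROIs recorded in the result).
#' @param seed integer RNG seed; same seed gives bit-identical noise.
#' @return an object of class `kspace_sample`: list with `data` (noisy
#'   k-space), `n`, `noise_sigma`, `target_snr`, `seed`.
#' @export
add_noise_for_target_snr <- function(kspace, target_snr, phantom, seed = 1) {
  check_square(kspace, "kspace")
  stopifnot(inherits(phantom, "mrm_phantom"))
  n <- nrow(kspace)
  if (n != phantom$n) stop("kspace size does not match phantom")
  infinite <- identical(target_snr, "infinite") ||
    (is.numeric(target_snr) && is.infinite(target_snr))
  if (!infinite && (!is.numeric(target_snr) || target_snr <= 0))
    stop("target_snr must be positive or \"infinite\"")

  if (infinite) {
    data <- as_complex_matrix(kspace)
    sigma <- 0
  } else {
    s_target <- mean(roi_pixels(phantom$image, phantom$signal_roi))
    sigma <- s_target / target_snr
    data <- with_seed(seed, {
      as_complex_matrix(kspace) +
        matrix(complex(real = rnorm(n * n, sd = sigma),
                       imaginary = rnorm(n * n, sd = sigma)), n, n)
    })
  }
  structure(list(data = data, n = n, noise_sigma = sigma,
                 target_snr = if (infinite) Inf else target_snr, seed = seed),
            class = "kspace_sample")
}

#' @export
print.kspace_sample <- function(x, ...) {
  cat(sprintf("<kspace_sample> %d x %d, noise sigma %.4g, target SNR %s\n",
              x$n, x$n, x$noise_sigma, format(x$target_snr)))
  invisible(x)
}

# accept either a kspace_sample or a bare complex matrix
kspace_data <- function(kspace) {
  if (inherits(kspace, "kspace_sample")) kspace$data
  else as_complex_matrix(check_square(kspace, "kspace"))
}
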