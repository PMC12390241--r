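# Cartesian undersampling masks: fully sampled central calibration disk plus
# weighted random samples outside it, with an exact acceleration-factor
# budget round(N^2 / AF).

#' Construct an undersampling mask
#'
#' All k-space points within `center_radius` (index units) of the DC index are
#' acquired; the remaining budget `round(n^2/af) - |disk|` is drawn without
#' replacement from the outside-disk points with probability proportional to
#' the sampling density `rho`:
#' * pattern 1: uniform,
#' * patterns 2 and 3: `rho ~ exp(-(kx^2 + ky^2) / (2 sigma_s^2))` in
#'   normalized coordinates with `k_max = 1` along each axis; `sigma_s = 2`
#'   (pattern 2) and `sigma_s = 4` (pattern 3), so pattern 2 is the more
#'   center-weighted of the two.
#'
#' The fully sampled disk counts toward the budget, so the retained fraction
#' is exactly `1/af`. Weighted sampling without replacement uses
#' exponential-key ranking (`rexp(n)/w`, keep the smallest), which is
#' distributionally identical to sequential weighted draws.
#'
#' @param n mask side in pixels.
#' @param af acceleration factor (>= 1); `af = 1` returns the full mask.
#' @param pattern 1, 2 or 3.
#' @param center_radius radius of the fully sampled disk in index units.
#' @param sigma_s density standard deviation in normalized k-units; default 2
#'   for pattern 2, 4 for pattern 3, unused for pattern 1.
#' @param seed integer RNG seed; masks are deterministic given the seed.
#' @return an object of class `sampling_mask`: list with `mask` (logical
#'   `n x n`), `pattern`, `af`, `center_radius`, `sigma_s`, `seed`, `n`.
#' @export
make_sampling_mask <- function(n, af, pattern, center_radius = 30,
                               sigma_s = NULL, seed = 1) {
  if (!pattern %in% 1:3) stop("pattern must be 1, 2 or 3")
  if (af < 1) stop("af must be >= 1")
  if (is.null(sigma_s)) sigma_s <- switch(pattern, NA_real_, 2, 4)

  budget <- round(n^2 / af)
  ic <- n / 2 + 1  # 1-based DC index for even n
  dr <- (seq_len(n) - ic)
  D2 <- outer(dr^2, dr^2, `+`)
  disk <- D2 <= center_radius^2
  n_disk <- sum(disk)
  if (budget < n_disk)
    stop(sprintf(
      "AF %.3g infeasible: budget %d smaller than the %d-point calibration disk (max feasible AF %.2f)",
      af, budget, n_disk, n^2 / n_disk))

  mask <- disk
  b_out <- budget - n_disk
  if (b_out > 0) {
    outside <- which(!disk)
    if (b_out > length(outside)) b_out <- length(outside)
    if (pattern == 1) {
      w <- rep(1, length(outside))
    } else {
      kx <- dr / (n / 2)  # normalized so k_max = 1 along each axis
      K2 <- outer(kx^2, kx^2, `+`)
      w <- exp(-K2[outside] / (2 * sigma_s^2))
    }
    keys <- with_seed(seed, rexp(length(outside)) / w)
    sel <- outside[order(keys)[seq_len(b_out)]]
    mask[sel] <- TRUE
  }
  stopifnot(sum(mask) == min(budget, n^2))
  structure(list(mask = mask, pattern = pattern, af = af,
                 center_radius = center_radius, sigma_s = sigma_s,
                 seed = seed, n = n),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf(
    "<sampling_mask> %d x %d, pattern %d, AF %.3g (achieved %.4g), disk radius %g\n",
    x$n, x$n, x$pattern, x$af, achieved_af(x), x$center_radius))
  invisible(x)
}

#' Achieved acceleration factor
#'
#' `n^2 / count(acquired)` for a mask.
#'
#' @param mask a [make_sampling_mask()] object or a logical matrix.
#' @return a single number.
#' @export
achieved_af <- function(mask) {
  m <- mask_matrix(mask)
  k <- sum(m)
  if (k == 0) stop("empty mask")
  length(m) / k
}

# accept a sampling_mask, a logical matrix, or a 0/1 matrix
mask_matrix <- function(mask) {
  if (inherits(mask, "sampling_mask")) return(mask$mask)
  if (is.matrix(mask)) return(mask != 0)
  stop("not a mask")
}
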