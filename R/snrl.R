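# SNR_L: the lowest image SNR at which the estimated resolution beta stays at
# or below the voxel size, found by linear interpolation of the mean
# beta-versus-SNR curve.

#' Interpolate the lower SNR limit
#'
#' Scans the mean beta-versus-SNR curve for downward crossings of `threshold`
#' and linearly interpolates the highest-SNR crossing (so beta <= threshold is
#' guaranteed for every larger grid SNR — SNR_L is read as a guarantee
#' threshold when sampling noise makes the curve non-monotone).
#'
#' @param snr_grid strictly ascending SNR values (length >= 2).
#' @param beta_means mean beta per SNR, same length.
#' @param threshold resolution threshold in pixels (voxel size; default 1).
#' @return list with `value` (interpolated SNR_L, or `NA`) and `status`: one
#'   of `"ok"` (crossing found), `"na"` (beta above threshold at the top of
#'   the grid: no SNR on the grid preserves resolution), `"le_min"` (beta at
#'   or below threshold everywhere: SNR_L is at most the grid minimum).
#' @export
compute_snr_l <- function(snr_grid, beta_means, threshold = 1.0) {
  if (length(snr_grid) != length(beta_means)) stop("length mismatch")
  if (length(snr_grid) < 2) stop("need at least 2 grid points")
  if (any(diff(snr_grid) <= 0)) stop("snr_grid must be strictly ascending")
  if (any(!is.finite(beta_means))) stop("beta means must be finite")

  k <- length(snr_grid)
  if (all(beta_means <= threshold))
    return(list(value = NA_real_, status = "le_min"))
  if (beta_means[k] > threshold)
    return(list(value = NA_real_, status = "na"))
  cross <- which(beta_means[-k] > threshold & beta_means[-1] <= threshold)
  j <- max(cross)
  v <- snr_grid[j] + (beta_means[j] - threshold) *
    (snr_grid[j + 1] - snr_grid[j]) / (beta_means[j] - beta_means[j + 1])
  list(value = v, status = "ok")
}

#' Aggregate per-trial resolution estimates into an SNR_L curve
#'
#' Computes the per-SNR mean and population variance of beta over trials and
#' interpolates SNR_L via [compute_snr_l()].
#'
#' @param per_trial_betas numeric matrix, trials in rows, SNR levels in
#'   columns (column order matching `snr_grid`).
#' @param snr_grid ascending SNR values.
#' @param threshold resolution threshold in pixels.
#' @return an object of class `snrl_curve`: `snr_grid`, `beta_mean`,
#'   `beta_var` (population variance), `n_trials`, `snr_l`, `status`,
#'   `threshold`.
#' @export
aggregate_trials <- function(per_trial_betas, snr_grid, threshold = 1.0) {
  m <- as.matrix(per_trial_betas)
  if (ncol(m) != length(snr_grid)) stop("column count must match snr_grid")
  if (nrow(m) < 1) stop("need at least one trial")
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing (trial, SNR) cells: ",
         paste(sprintf("(%d, %g)", bad[, 1], snr_grid[bad[, 2]]),
               collapse = ", "))
  }
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2  # population variance
  sl <- compute_snr_l(snr_grid, mu, threshold)
  structure(list(snr_grid = snr_grid, beta_mean = mu, beta_var = va,
                 n_trials = nrow(m), snr_l = sl$value, status = sl$status,
                 threshold = threshold),
            class = "snrl_curve")
}

#' @export
print.snrl_curve <- function(x, ...) {
  cat(sprintf("<snrl_curve> %d SNR levels x %d trials, threshold %g px\n",
              length(x$snr_grid), x$n_trials, x$threshold))
  lab <- switch(x$status,
                ok = sprintf("SNR_L = %.4g", x$snr_l),
                na = "SNR_L = NA (resolution not preserved on the grid)",
                le_min = sprintf("SNR_L <= %g (preserved everywhere)",
                                 min(x$snr_grid)))
  cat(" ", lab, "\n")
  invisible(x)
}

#' SNR_L curve as a data.frame
#'
#' One row per SNR level, for CSV export.
#'
#' @param x an `snrl_curve`.
#' @param ... unused.
#' @return data.frame with columns `snr`, `beta_mean`, `beta_var`, `n_trials`.
#' @export
as.data.frame.snrl_curve <- function(x, ...) {
  data.frame(snr = x$snr_grid, beta_mean = x$beta_mean, beta_var = x$beta_var,
             n_trials = x$n_trials)
}
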