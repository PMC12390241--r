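# Classical reconstruction baselines: zero-filling and L1-wavelet compressed
# sensing solved by monotone FISTA.

new_recon_result <- function(image, method, params = list(),
                             objective_trace = NULL) {
  structure(list(image = image, magnitude = Mod(image), method = method,
                 params = params, objective_trace = objective_trace),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s, %d x %d\n", x$method,
              nrow(x$image), ncol(x$image)))
  if (!is.null(x$objective_trace))
    cat(sprintf("  %d iterations, final objective %.6g\n",
                length(x$objective_trace),
                x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Zero-filled reconstruction
#'
#' Inverse transform of the mask-multiplied k-space: unacquired samples are
#' set to zero. The artifact-laden baseline every other method is compared
#' against.
#'
#' @param kspace complex k-space matrix or [add_noise_for_target_snr()] result.
#' @param mask a [make_sampling_mask()] object or logical matrix.
#' @return a `recon_result` with complex `image` and real `magnitude`.
#' @export
zero_fill_recon <- function(kspace, mask) {
  y <- kspace_data(kspace)
  m <- mask_matrix(mask)
  if (!all(dim(m) == dim(y))) stop("mask and kspace shapes differ")
  img <- kspace_to_image(y * m)
  new_recon_result(img, "zero_fill",
                   params = list(af = length(m) / max(1, sum(m))))
}

#' L1-wavelet compressed-sensing reconstruction
#'
#' Approximately minimizes `0.5 * ||M (F x - y)||^2 + lam * ||Psi x||_1` by
#' monotone FISTA (accelerated proximal gradient with a monotone acceptance
#' step), where `F` is the unitary centered DFT, `M` the sampling mask, and
#' `Psi` an orthonormal periodic Daubechies-4 wavelet transform with `levels`
#' decomposition levels applied to the complex image. The forward operator has
#' unit Lipschitz constant under the unitary convention, so the step size is
#' 1. `lam` is interpreted on data normalized so the zero-filled magnitude
#' maximum is 1; the returned image is rescaled to the input's units, the
#' objective trace is in normalized units.
#'
#' @param kspace complex k-space matrix or [add_noise_for_target_snr()] result.
#' @param mask a [make_sampling_mask()] object or logical matrix.
#' @param lam regularization weight (default `2e-3`).
#' @param max_iters iteration cap (default 200).
#' @param tol stop when the relative image change drops below this (default
#'   `1e-6`).
#' @param levels wavelet decomposition levels (default 4; the image side must
#'   be divisible by `2^levels`).
#' @return a `recon_result`; `objective_trace` holds the per-iteration
#'   objective, non-increasing by construction.
#' @export
cs_l1wavelet_recon <- function(kspace, mask, lam = 2e-3, max_iters = 200,
                               tol = 1e-6, levels = 4) {
  y <- kspace_data(kspace)
  m <- mask_matrix(mask)
  if (!all(dim(m) == dim(y))) stop("mask and kspace shapes differ")
  if (lam < 0) stop("lam must be >= 0")
  n <- nrow(y)
  if (n %% 2^levels != 0) stop("image side must be divisible by 2^levels")

  ym <- y * m
  zf <- kspace_to_image(ym)
  sc <- max(Mod(zf))
  if (sc == 0) {
    return(new_recon_result(zf, "cs_l1w",
                            params = list(lam = lam, max_iters = max_iters,
                                          tol = tol, levels = levels),
                            objective_trace = 0))
  }
  fit <- cpp_cs_fista(ym / sc, m * 1, lam, as.integer(max_iters), tol,
                      as.integer(levels))
  new_recon_result(fit$image * sc, "cs_l1w",
                   params = list(lam = lam, max_iters = max_iters, tol = tol,
                                 levels = levels, scale = sc,
                                 iters = fit$iters),
                   objective_trace = fit$trace)
}

#' Orthonormal periodic Daubechies-4 wavelet transform
#'
#' Forward/inverse 2-D separable transform used by [cs_l1wavelet_recon()],
#' exposed for diagnostics and testing. Orthonormal: energy is conserved and
#' `idwt2(dwt2(x)) == x` to machine precision.
#'
#' @param x real square matrix, side divisible by `2^levels`.
#' @param w wavelet coefficient matrix in Mallat layout.
#' @param levels number of decomposition levels.
#' @return matrix of the input size.
#' @export
dwt2 <- function(x, levels = 4) {
  check_square(x, "x")
  cpp_dwt2(x, as.integer(levels))
}

#' @rdname dwt2
#' @export
idwt2 <- function(w, levels = 4) {
  check_square(w, "w")
  cpp_idwt2(w, as.integer(levels))
}
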