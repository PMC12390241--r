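# Scan-specific zero-shot self-supervised reconstruction: the acquired
# k-space Omega is partitioned into Theta (data consistency during training),
# Lambda (training loss) and Gamma (validation loss for early stopping). An
# unrolled network alternates a ResNet denoiser with closed-form single-coil
# data consistency; after early stopping the full measurement set is passed
# through the trained network.

#' Partition acquired k-space into training/loss/validation subsets
#'
#' Draws Gamma uniformly from the acquired set Omega at `gamma_fraction`, then
#' Lambda from the remainder at `lam_fraction`; everything else is Theta. With
#' `center_to_theta` (default) the fully sampled calibration disk is always
#' assigned to Theta so the network input retains the low-frequency core.
#'
#' @param mask a [make_sampling_mask()] object (or logical matrix, in which
#'   case no calibration disk is known and `center_to_theta` is ignored).
#' @param gamma_fraction,lam_fraction fractions in (0, 1).
#' @param seed integer RNG seed.
#' @param center_to_theta keep the calibration disk in Theta.
#' @return an object of class `split_masks`: logical matrices `theta`, `lam`,
#'   `gamma` (pairwise disjoint, union = Omega), achieved `fractions`, `seed`.
#' @export
split_measurements <- function(mask, gamma_fraction = 0.2, lam_fraction = 0.4,
                               seed = 1, center_to_theta = TRUE) {
  m <- mask_matrix(mask)
  if (gamma_fraction <= 0 || gamma_fraction >= 1 ||
      lam_fraction <= 0 || lam_fraction >= 1)
    stop("fractions must lie in (0, 1)")
  omega <- which(m)
  n_omega <- length(omega)
  if (n_omega < 3) stop("mask has fewer than 3 acquired points")

  fixed <- integer(0)
  if (center_to_theta && inherits(mask, "sampling_mask")) {
    n <- mask$n
    ic <- n / 2 + 1
    dr <- seq_len(n) - ic
    disk <- outer(dr^2, dr^2, `+`) <= mask$center_radius^2
    fixed <- which(disk & m)
  }
  free <- setdiff(omega, fixed)

  n_gamma <- round(gamma_fraction * n_omega)
  if (n_gamma < 1 || n_gamma > length(free) - 1)
    stop("gamma_fraction leaves an empty subset")
  sel <- with_seed(seed, {
    gamma_idx <- sample(free, n_gamma)
    rest <- setdiff(free, gamma_idx)
    n_lam <- round(lam_fraction * (n_omega - n_gamma))
    if (n_lam < 1 || n_lam > length(rest) - (if (length(fixed)) 0 else 1))
      stop("lam_fraction leaves an empty subset")
    lam_idx <- sample(rest, n_lam)
    list(gamma = gamma_idx, lam = lam_idx)
  })
  theta_idx <- setdiff(omega, c(sel$gamma, sel$lam))
  if (!length(theta_idx)) stop("Theta subset is empty")

  dim_n <- dim(m)
  mk <- function(idx) {
    x <- matrix(FALSE, dim_n[1], dim_n[2])
    x[idx] <- TRUE
    x
  }
  structure(list(theta = mk(theta_idx), lam = mk(sel$lam),
                 gamma = mk(sel$gamma),
                 fractions = c(theta = length(theta_idx) / n_omega,
                               lam = length(sel$lam) / n_omega,
                               gamma = length(sel$gamma) / n_omega),
                 seed = seed),
            class = "split_masks")
}

#' @export
print.split_masks <- function(x, ...) {
  cat(sprintf("<split_masks> theta %.3f, lambda %.3f, gamma %.3f of Omega\n",
              x$fractions["theta"], x$fractions["lam"], x$fractions["gamma"]))
  invisible(x)
}

#' Data-consistency solve
#'
#' Solves `(E^H E + mu I) x = E^H y + mu z` with `E = mask o F` by conjugate
#' gradients in the image domain. For single-coil Cartesian data the operator
#' is diagonal in k-space (eigenvalues `mu` and `1 + mu`), so CG converges in
#' two iterations; the closed form `X = (Y + mu Z) / (1 + mu)` on sampled and
#' `X = Z` on unsampled points is used as the independent test oracle. CG is
#' retained as the implementation to keep the multi-coil extension path.
#'
#' @param z complex image (the denoiser output / prior).
#' @param y measured k-space (complex matrix, values outside the subset are
#'   ignored).
#' @param subset_mask logical matrix of points participating in data
#'   consistency.
#' @param mu non-negative weight on the prior term.
#' @param cg_iters maximum CG iterations.
#' @param tol CG residual tolerance (relative to the right-hand side norm).
#' @return complex image; attributes `cg_iters`, `cg_relres` and
#'   `cg_converged` record the solve.
#' @export
dc_solve <- function(z, y, subset_mask, mu, cg_iters = 10, tol = 1e-10) {
  if (mu < 0) stop("mu must be >= 0")
  m <- mask_matrix(subset_mask)
  z <- as_complex_matrix(z)
  y <- kspace_data(y)
  A <- function(x) kspace_to_image(image_to_kspace(x) * m) + mu * x
  rhs <- kspace_to_image(y * m) + mu * z
  x <- z  # warm start at the prior
  r <- rhs - A(x)
  p <- r
  rs <- sum(Mod(r)^2)
  rhs_n <- sqrt(sum(Mod(rhs)^2))
  it <- 0
  while (it < cg_iters && sqrt(rs) > tol * max(rhs_n, 1e-300)) {
    it <- it + 1
    Ap <- A(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  relres <- sqrt(rs) / max(rhs_n, 1e-300)
  converged <- relres <= tol
  if (!converged)
    warning(sprintf("dc_solve CG did not converge in %d iterations (relres %.2e)",
                    cg_iters, relres))
  attr(x, "cg_iters") <- it
  attr(x, "cg_relres") <- relres
  attr(x, "cg_converged") <- converged
  x
}

#' Mixed L1/L2 training loss
#'
#' `L(u, v) = ||u - v||_1 / ||u||_1 + ||u - v||_2 / ||u||_2` on complex (or
#' real) vectors; scale-invariant and 0 iff `u == v`.
#'
#' @param u reference vector (must not be identically zero).
#' @param v prediction vector of the same length.
#' @return a single number.
#' @export
mixed_norm_loss <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  n1 <- sum(Mod(u)); n2 <- sqrt(sum(Mod(u)^2))
  if (n1 == 0) stop("reference vector is identically zero")
  sum(Mod(u - v)) / n1 + sqrt(sum(Mod(u - v)^2)) / n2
}

#' Unrolled network configuration
#'
#' Architecture and training settings for the zero-shot self-supervised
#' reconstruction. Defaults follow the reference protocol: 10 unrolls of
#' data consistency + denoising, a ResNet denoiser with 5 residual blocks
#' (conv-ReLU-conv-scale, scale `alpha = 0.1`) of 64 filters with 3x3 kernels
#' on a two-channel real/imaginary representation, Adam at learning rate
#' 5e-4, and early stopping on the validation subset with patience 20.
#'
#' @param unrolls data-consistency/denoiser alternations.
#' @param residual_blocks ResNet blocks in the denoiser.
#' @param filters convolution filters per layer.
#' @param scale_alpha residual scaling factor.
#' @param learning_rate Adam step size.
#' @param mu_init initial value of the learnable data-consistency weight.
#' @param cg_iters CG iterations for [dc_solve()] when used stand-alone.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without a new validation
#'   minimum under the default rule; consecutive `L_train > L_val` epochs
#'   under the literal rule).
#' @param gamma_fraction,lam_fraction k-space split fractions
#'   (see [split_measurements()]).
#' @param center_to_theta keep the calibration disk in Theta.
#' @param early_stopping `"best_val"` (default): stop after `patience` epochs
#'   without a new validation-loss minimum and restore the checkpoint at the
#'   minimum. `"literal"`: stop once `L_train > L_val` for `patience`
#'   consecutive epochs, keeping the final parameters.
#' @param seed RNG seed for the split and weight initialization.
#' @return an object of class `zs_config`.
#' @export
zs_ssl_config <- function(unrolls = 10, residual_blocks = 5, filters = 64,
                          scale_alpha = 0.1, learning_rate = 5e-4,
                          mu_init = 0.05, cg_iters = 10, max_epochs = 500,
                          patience = 20, gamma_fraction = 0.2,
                          lam_fraction = 0.4, center_to_theta = TRUE,
                          early_stopping = c("best_val", "literal"),
                          seed = 1) {
  early_stopping <- match.arg(early_stopping)
  cfg <- list(unrolls = as.integer(unrolls),
              residual_blocks = as.integer(residual_blocks),
              filters = as.integer(filters), kernel = 3L,
              scale_alpha = scale_alpha, learning_rate = learning_rate,
              mu_init = mu_init, cg_iters = as.integer(cg_iters),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              gamma_fraction = gamma_fraction, lam_fraction = lam_fraction,
              center_to_theta = center_to_theta,
              early_stopping = early_stopping, seed = as.integer(seed))
  if (any(unlist(cfg[c("unrolls", "residual_blocks", "filters", "max_epochs",
                       "patience", "cg_iters")]) < 1))
    stop("all counts must be positive")
  if (mu_init <= 0) stop("mu_init must be positive")
  structure(cfg, class = "zs_config")
}

#' @export
print.zs_config <- function(x, ...) {
  cat(sprintf(
    "<zs_config> %d unrolls, %d blocks x %d filters, alpha %.2g, lr %.2g, %s stopping (patience %d)\n",
    x$unrolls, x$residual_blocks, x$filters, x$scale_alpha, x$learning_rate,
    x$early_stopping, x$patience))
  invisible(x)
}

# He-normal weight init; final conv zero so the initial network is the
# identity and the first unrolls reduce to repeated data consistency.
zs_init_params <- function(config) {
  f <- config$filters
  B <- config$residual_blocks
  he <- function(cin, cout) matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                                   9 * cin, cout)
  with_seed(config$seed, {
    list(W_in = he(2, f), b_in = rep(0, f),
         W1 = lapply(seq_len(B), function(i) he(f, f)),
         b1 = lapply(seq_len(B), function(i) rep(0, f)),
         W2 = lapply(seq_len(B), function(i) he(f, f)),
         b2 = lapply(seq_len(B), function(i) rep(0, f)),
         W_out = matrix(0, 9 * f, 2), b_out = rep(0, 2),
         mu = config$mu_init)
  })
}

#' Run the unrolled network
#'
#' Alternates the ResNet denoiser and single-coil data consistency for
#' `config$unrolls` iterations, starting from the zero-filled image of the
#' subset data. With zero-initialized convolution weights the denoiser is the
#' identity, and the output reduces to repeated data consistency on the
#' zero-filled image.
#'
#' @param y_subset complex k-space matrix (values outside `subset_mask` are
#'   ignored).
#' @param subset_mask logical matrix: the encoder operator's sampling set.
#' @param params network parameters (from [train_zs_ssl()] or
#'   `mrmbench:::zs_init_params`).
#' @param config a [zs_ssl_config()].
#' @return complex image matrix.
#' @export
unrolled_forward <- function(y_subset, subset_mask, params, config) {
  m <- mask_matrix(subset_mask)
  y <- kspace_data(y_subset)
  out <- cpp_zs_forward(params, y, m * 1L, m * 1L, config$unrolls,
                        config$residual_blocks, config$scale_alpha)
  if (any(!is.finite(Re(out)))) stop("non-finite activations in unrolled network")
  out
}

# one Adam update over the nested parameter list (mu clamped positive)
adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, key) {
    m <- state$m[[key]]; v <- state$v[[key]]
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[key]] <- m   # state is an environment: reference semantics
    state$v[[key]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p - lr * mhat / (sqrt(vhat) + eps)
  }
  for (nm in c("W_in", "b_in", "W_out", "b_out")) {
    params[[nm]] <- upd(params[[nm]], grads[[nm]], nm)
  }
  for (nm in c("W1", "b1", "W2", "b2")) {
    for (b in seq_along(params[[nm]])) {
      params[[nm]][[b]] <- upd(params[[nm]][[b]], grads[[nm]][[b]],
                               paste0(nm, b))
    }
  }
  params$mu <- max(1e-6, upd(params$mu, grads$mu, "mu"))
  list(params = params, state = state)
}

#' Train the zero-shot self-supervised reconstruction
#'
#' Each epoch computes the training loss
#' `L_train = L(y_Lambda, E_Lambda f(y_Theta, E_Theta))` — the network sees
#' only Theta and is scored on its k-space prediction at Lambda — updates the
#' parameters with Adam on `L_train`, then computes the validation loss
#' `L_val = L(y_Gamma, E_Gamma f(y_{Omega minus Gamma}, E_{Omega minus
#' Gamma}))`, the prediction of the held-out Gamma samples. Stopping follows
#' `config$early_stopping`. K-space is scaled so the zero-filled magnitude
#' maximum is 1 before training; the scale is recorded for inference.
#'
#' @param kspace complex k-space matrix or [add_noise_for_target_snr()] result.
#' @param mask the acquisition [make_sampling_mask()].
#' @param config a [zs_ssl_config()].
#' @return an object of class `zs_fit`: `params` (trained weights), `history`
#'   (data.frame epoch/train/val), `stop_epoch`, `stop_reason`, `scale`,
#'   `splits`, `mask`, `config`.
#' @export
train_zs_ssl <- function(kspace, mask, config = zs_ssl_config()) {
  stopifnot(inherits(config, "zs_config"))
  y <- kspace_data(kspace)
  m <- mask_matrix(mask)
  if (!all(dim(m) == dim(y))) stop("mask and kspace shapes differ")

  splits <- split_measurements(mask, config$gamma_fraction,
                               config$lam_fraction, seed = config$seed,
                               center_to_theta = config$center_to_theta)
  ym <- y * m
  sc <- max(Mod(kspace_to_image(ym)))
  if (sc == 0) stop("k-space is identically zero")
  yn <- ym / sc

  params <- zs_init_params(config)
  state <- new.env()
  state$t <- 0; state$m <- list(); state$v <- list()

  theta <- splits$theta * 1L
  lam <- splits$lam * 1L
  gamma <- splits$gamma * 1L
  not_gamma <- (m & !splits$gamma) * 1L

  hist_train <- numeric(0)
  hist_val <- numeric(0)
  best_val <- Inf
  best_params <- params
  best_epoch <- 0L
  bad_epochs <- 0L
  literal_run <- 0L
  stop_reason <- "max_epochs"
  U <- config$unrolls; B <- config$residual_blocks; al <- config$scale_alpha

  for (epoch in seq_len(config$max_epochs)) {
    tr <- cpp_zs_loss_grad(params, yn, theta, theta, lam, U, B, al, TRUE)
    if (!is.finite(tr$loss)) {
      stop(structure(class = c("zs_training_error", "error", "condition"),
                     list(message = sprintf(
                       "non-finite training loss at epoch %d", epoch),
                       call = sys.call(),
                       history = data.frame(epoch = seq_along(hist_train),
                                            train = hist_train,
                                            val = hist_val))))
    }
    ad <- adam_update(params, tr$grads, state, config$learning_rate)
    params <- ad$params
    vl <- cpp_zs_loss_grad(params, yn, not_gamma, not_gamma, gamma, U, B, al,
                           FALSE)
    hist_train <- c(hist_train, tr$loss)
    hist_val <- c(hist_val, vl$loss)

    if (config$early_stopping == "best_val") {
      if (vl$loss < best_val) {
        best_val <- vl$loss
        best_params <- params
        best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) {
          stop_reason <- "patience"
          break
        }
      }
    } else {  # literal printed rule: L_train > L_val for `patience` epochs
      literal_run <- if (tr$loss > vl$loss) literal_run + 1L else 0L
      if (literal_run >= config$patience) {
        stop_reason <- "literal_rule"
        best_params <- params
        best_epoch <- epoch
        break
      }
    }
  }
  if (config$early_stopping == "literal" && stop_reason == "max_epochs") {
    best_params <- params
    best_epoch <- length(hist_train)
  }
  if (config$early_stopping == "best_val" && best_epoch == 0L) {
    best_params <- params
    best_epoch <- length(hist_train)
  }

  structure(list(params = best_params,
                 history = data.frame(epoch = seq_along(hist_train),
                                      train = hist_train, val = hist_val),
                 stop_epoch = length(hist_train),
                 best_epoch = best_epoch,
                 stop_reason = stop_reason,
                 scale = sc, splits = splits, mask = m, config = config),
            class = "zs_fit")
}

#' @export
print.zs_fit <- function(x, ...) {
  cat(sprintf(
    "<zs_fit> stopped at epoch %d (%s), best epoch %d, val loss %.5g\n",
    x$stop_epoch, x$stop_reason, x$best_epoch, x$history$val[x$best_epoch]))
  invisible(x)
}

#' Final zero-shot reconstruction
#'
#' Passes the entire measured k-space through the trained unrolled network
#' (subset = Omega) and rescales to the input units.
#'
#' @param kspace the same k-space the network was trained on.
#' @param mask the acquisition mask used in training.
#' @param fit a [train_zs_ssl()] result.
#' @param config configuration; defaults to the one stored in `fit`.
#' @return a `recon_result`.
#' @export
zs_ssl_reconstruct <- function(kspace, mask, fit, config = fit$config) {
  stopifnot(inherits(fit, "zs_fit"))
  m <- mask_matrix(mask)
  if (!identical(dim(m), dim(fit$mask)) || !all(m == fit$mask))
    stop("mask does not match the mask the network was trained on")
  y <- kspace_data(kspace)
  img <- cpp_zs_forward(fit$params, y * m / fit$scale, m * 1L, m * 1L,
                        config$unrolls, config$residual_blocks,
                        config$scale_alpha) * fit$scale
  new_recon_result(img, "zs_ssl",
                   params = list(config = config, stop_epoch = fit$stop_epoch,
                                 best_epoch = fit$best_epoch,
                                 stop_reason = fit$stop_reason))
}

#' One-call ZS-SSL reconstruction
#'
#' Convenience wrapper: [train_zs_ssl()] followed by [zs_ssl_reconstruct()].
#'
#' @inheritParams train_zs_ssl
#' @return a `recon_result`; the `zs_fit` is attached as `$params$fit`.
#' @export
zs_ssl_recon <- function(kspace, mask, config = zs_ssl_config()) {
  fit <- train_zs_ssl(kspace, mask, config)
  out <- zs_ssl_reconstruct(kspace, mask, fit)
  out$params$fit <- fit
  out
}
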