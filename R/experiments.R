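# Orchestration of the simulation grid: method x AF x SNR x pattern x trial,
# deterministic per-cell seeding, aggregation into SNR_L curves and a summary
# table in the method-by-AF layout.

#' Simulation grid configuration
#'
#' @param n image side in pixels. Geometry (phantom layout, and
#'   `center_radius` when left `NULL`) scales with `n/512` so that smaller
#'   grids are geometric miniatures of the 512-pixel reference protocol.
#' @param methods subset of `"zero_fill"`, `"cs_l1w"`, `"zs_ssl"`.
#' @param afs acceleration factors (reference protocol: 2, 4, 6, 8).
#' @param snr_levels SNR grid (reference protocol: 4, 6, 8, 10, 15, 20, 30,
#'   50, 100).
#' @param patterns sampling patterns, subset of 1:3.
#' @param n_trials trials per cell (reference protocol: 10); each trial
#'   redraws both the mask and the noise.
#' @param base_seed integer; all cell seeds derive deterministically from it.
#' @param structure_for_beta label of the structure whose window the blur is
#'   fitted on (default the 20-px circle, `"circle_20"`).
#' @param center_radius calibration-disk radius; `NULL` scales the reference
#'   30 px by `n/512`.
#' @param supersample phantom supersampling factor.
#' @param cs list of [cs_l1wavelet_recon()] settings.
#' @param zs a [zs_ssl_config()] (its `seed` is replaced per cell).
#' @param sigma_bounds blur-fit search interval in pixels.
#' @param threshold resolution threshold in pixels for SNR_L.
#' @param output_dir optional directory for per-cell CSV records; completed
#'   cells found there are skipped on re-run (resume).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n = 512,
                              methods = c("zero_fill", "cs_l1w", "zs_ssl"),
                              afs = c(2, 4, 6, 8),
                              snr_levels = c(4, 6, 8, 10, 15, 20, 30, 50, 100),
                              patterns = 2,
                              n_trials = 10,
                              base_seed = 1,
                              structure_for_beta = "circle_20",
                              center_radius = NULL,
                              supersample = 8,
                              cs = list(lam = 2e-3, max_iters = 200,
                                        tol = 1e-6, levels = 4),
                              zs = zs_ssl_config(),
                              sigma_bounds = c(0.01, 20),
                              threshold = 1.0,
                              output_dir = NULL) {
  methods <- match.arg(methods, c("zero_fill", "cs_l1w", "zs_ssl"),
                       several.ok = TRUE)
  if (!length(afs) || any(afs < 1)) stop("afs must be >= 1")
  if (!length(snr_levels)) stop("empty snr_levels")
  if (!all(patterns %in% 1:3)) stop("patterns must be in 1:3")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (is.null(center_radius)) center_radius <- 30 * n / 512
  structure(list(n = n, methods = methods, afs = afs,
                 snr_levels = sort(snr_levels), patterns = patterns,
                 n_trials = n_trials, base_seed = as.integer(base_seed),
                 structure_for_beta = structure_for_beta,
                 center_radius = center_radius, supersample = supersample,
                 cs = cs, zs = zs, sigma_bounds = sigma_bounds,
                 threshold = threshold, output_dir = output_dir),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> n=%d, %s | AF {%s} x SNR {%s} x pattern {%s} x %d trials\n",
    x$n, paste(x$methods, collapse = "/"),
    paste(x$afs, collapse = ","), paste(x$snr_levels, collapse = ","),
    paste(x$patterns, collapse = ","), x$n_trials))
  invisible(x)
}

# phantom cache: one phantom per config (deterministic, noise-free)
config_phantom <- function(config) {
  generate_phantom(config$n, config$supersample, "paper-default")
}

#' Run one simulation cell
#'
#' Draws the cell's mask and noise from a seed derived deterministically from
#' `base_seed` and the cell coordinates, reconstructs, fits the blur on the
#' configured structure window, and records everything.
#'
#' @param config an [experiment_config()].
#' @param method,af,snr,pattern,trial cell coordinates. `snr` may be
#'   `"infinite"`/`Inf`.
#' @param phantom optionally, a pre-built phantom (avoids regeneration).
#' @return one-row data.frame: method, af, snr, pattern, trial, seed, sigma,
#'   beta, sse, boundary, nrmse, measured_snr, iters, elapsed.
#' @export
run_condition <- function(config, method, af, snr, pattern, trial,
                          phantom = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(phantom)) phantom <- config_phantom(config)
  t0 <- proc.time()[3]
  seed <- cell_seed(config$base_seed, method, af, snr, pattern, trial)

  mask <- make_sampling_mask(config$n, af, pattern,
                             center_radius = config$center_radius,
                             seed = seed)
  k0 <- image_to_kspace(phantom$image)
  kn <- add_noise_for_target_snr(k0, snr, phantom, seed = seed + 1L)

  iters <- NA_real_
  rec <- switch(method,
    zero_fill = zero_fill_recon(kn, mask),
    cs_l1w = {
      r <- cs_l1wavelet_recon(kn, mask, lam = config$cs$lam,
                              max_iters = config$cs$max_iters,
                              tol = config$cs$tol, levels = config$cs$levels)
      iters <- r$params$iters
      r
    },
    zs_ssl = {
      zcfg <- config$zs
      zcfg$seed <- seed + 2L
      r <- zs_ssl_recon(kn, mask, zcfg)
      iters <- r$params$fit$stop_epoch
      r
    },
    stop("unknown method: ", method))

  win <- structure_window(phantom, config$structure_for_beta)
  est <- fit_blur_sigma(rec$magnitude, phantom$image, win,
                        sigma_bounds = config$sigma_bounds,
                        signal_roi = phantom$signal_roi)
  msnr <- if (kn$noise_sigma > 0)
    measure_snr(rec$magnitude, phantom$signal_roi, phantom$background_roi)
  else NA_real_

  data.frame(method = method, af = af,
             snr = if (identical(snr, "infinite")) Inf else snr,
             pattern = pattern, trial = trial, seed = seed,
             sigma = est$sigma, beta = est$beta, sse = est$sse,
             boundary = est$boundary,
             nrmse = nrmse(rec$magnitude, phantom$image),
             measured_snr = msnr, iters = iters,
             elapsed = proc.time()[3] - t0,
             stringsAsFactors = FALSE)
}

cell_file <- function(dir, method, af, snr, pattern, trial) {
  file.path(dir, sprintf("cell_%s_af%g_snr%s_p%d_t%d.csv",
                         method, af, format(snr), pattern, trial))
}

#' Run the full simulation grid
#'
#' Executes every (method, AF, SNR, pattern, trial) cell, aggregates the
#' per-trial beta estimates into an [aggregate_trials()] curve per
#' method x AF x pattern, and assembles the summary table of SNR_L in the
#' method-by-AF layout. With `config$output_dir` set, per-cell records are
#' written as CSV and previously completed cells are skipped (resume).
#'
#' @param config an [experiment_config()].
#' @param phantom optionally a pre-built phantom.
#' @param progress print one line per cell.
#' @return an object of class `mrm_grid_result`: `records` (all trial rows),
#'   `curves` (named list of `snrl_curve`, names `method|af|pattern`),
#'   `summary` (data.frame method x AF of SNR_L values), `failed` (list of
#'   failed cells, normally empty).
#' @export
run_grid <- function(config, phantom = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(phantom)) phantom <- config_phantom(config)
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)

  cells <- expand.grid(trial = seq_len(config$n_trials),
                       snr = config$snr_levels, af = config$afs,
                       pattern = config$patterns, method = config$methods,
                       stringsAsFactors = FALSE)
  records <- vector("list", nrow(cells))
  failed <- list()
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    f <- if (!is.null(dir))
      cell_file(dir, ci$method, ci$af, ci$snr, ci$pattern, ci$trial) else NULL
    if (!is.null(f) && file.exists(f)) {
      records[[i]] <- read.csv(f, stringsAsFactors = FALSE)
      next
    }
    rec <- tryCatch(
      run_condition(config, ci$method, ci$af, ci$snr, ci$pattern, ci$trial,
                    phantom = phantom),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failed[[length(failed) + 1]] <- list(cell = ci, message = conditionMessage(rec))
      next
    }
    if (progress)
      message(sprintf("[%s af=%g snr=%s p=%d t=%d] beta=%.3f (%.1fs)",
                      ci$method, ci$af, format(ci$snr), ci$pattern, ci$trial,
                      rec$beta, rec$elapsed))
    if (!is.null(f)) write.csv(rec, f, row.names = FALSE)
    records[[i]] <- rec
  }
  if (length(failed)) {
    msg <- paste(vapply(failed, function(x)
      sprintf("%s af=%g snr=%s p=%d t=%d: %s", x$cell$method, x$cell$af,
              format(x$cell$snr), x$cell$pattern, x$cell$trial, x$message),
      character(1)), collapse = "\n  ")
    stop("failed cells:\n  ", msg)
  }
  records <- do.call(rbind, records)

  curves <- list()
  for (m in config$methods) for (a in config$afs) for (p in config$patterns) {
    sub <- records[records$method == m & records$af == a &
                     records$pattern == p & is.finite(records$snr), ]
    if (!nrow(sub)) next
    bm <- matrix(NA_real_, config$n_trials, length(config$snr_levels))
    for (j in seq_along(config$snr_levels))
      bm[, j] <- sub$beta[sub$snr == config$snr_levels[j]][seq_len(config$n_trials)]
    curves[[paste(m, a, p, sep = "|")]] <-
      aggregate_trials(bm, config$snr_levels, config$threshold)
  }

  summary <- expand.grid(method = config$methods, af = config$afs,
                         pattern = config$patterns, stringsAsFactors = FALSE)
  summary$snr_l <- NA_real_
  summary$status <- NA_character_
  for (r in seq_len(nrow(summary))) {
    cv <- curves[[paste(summary$method[r], summary$af[r], summary$pattern[r],
                        sep = "|")]]
    if (!is.null(cv)) {
      summary$snr_l[r] <- cv$snr_l
      summary$status[r] <- cv$status
    }
  }
  if (!is.null(dir)) {
    write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
    write.csv(summary, file.path(dir, "snrl_summary.csv"), row.names = FALSE)
    for (nm in names(curves))
      write.csv(as.data.frame(curves[[nm]]),
                file.path(dir, paste0("curve_", gsub("[|]", "_", nm), ".csv")),
                row.names = FALSE)
  }
  structure(list(records = records, curves = curves, summary = summary,
                 failed = failed, config = config),
            class = "mrm_grid_result")
}

#' @export
print.mrm_grid_result <- function(x, ...) {
  cat(sprintf("<mrm_grid_result> %d trial records\n", nrow(x$records)))
  print(x$summary)
  invisible(x)
}

#' Compare sampling patterns
#'
#' Runs the grid for each requested pattern at a single acceleration factor
#' and reports the per-pattern SNR_L curves and the pattern attaining the
#' lowest SNR_L.
#'
#' @param config an [experiment_config()] whose `methods` is a single
#'   reconstruction method (`"cs_l1w"` or `"zs_ssl"`).
#' @param af the acceleration factor to compare at (default 4).
#' @param phantom optionally a pre-built phantom.
#' @return list with `curves` (one `snrl_curve` per pattern), `snr_l` (named
#'   vector), `best_pattern`.
#' @export
compare_patterns <- function(config, af = 4, phantom = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$methods) != 1 ||
      !config$methods %in% c("cs_l1w", "zs_ssl"))
    stop("select a single reconstruction method (cs_l1w or zs_ssl)")
  cfg <- config
  cfg$afs <- af
  if (is.null(phantom)) phantom <- config_phantom(cfg)
  res <- run_grid(cfg, phantom = phantom)
  curves <- res$curves
  names(curves) <- sub("^.*\\|.*\\|", "pattern_", names(curves))
  vals <- vapply(curves, function(cv)
    if (cv$status == "ok") cv$snr_l
    else if (cv$status == "le_min") min(cv$snr_grid) else Inf, numeric(1))
  list(curves = curves, snr_l = vals,
       best_pattern = config$patterns[which.min(vals)])
}
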