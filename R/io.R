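# File interchange: NIfTI volumes (RNifti), PNG previews, raw binary + JSON
# sidecar for complex k-space, YAML run configuration.

#' Write an image or phantom as NIfTI
#'
#' @param x an `mrm_phantom`, `recon_result`, or real matrix.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(x, path) {
  img <- if (inherits(x, "mrm_phantom")) x$image
  else if (inherits(x, "recon_result")) x$magnitude
  else x
  if (is.complex(img)) img <- Mod(img)
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' Read a 2-D NIfTI image
#'
#' @param path NIfTI file path.
#' @return a matrix.
#' @export
read_image_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  as.matrix(drop(unclass(arr)))
}

#' Write a magnitude image (or mask) as PNG
#'
#' Magnitudes are min-max scaled to 16-bit gray; logical masks are written as
#' binary black/white.
#'
#' @param x matrix, `mrm_phantom`, `recon_result` or `sampling_mask`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  img <- if (inherits(x, "mrm_phantom")) x$image
  else if (inherits(x, "recon_result")) x$magnitude
  else if (inherits(x, "sampling_mask")) x$mask * 1
  else x
  if (is.complex(img)) img <- Mod(img)
  rng <- range(img)
  sc <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  png::writePNG(sc, path)
  invisible(path)
}

#' Save complex k-space
#'
#' Paired real/imaginary NIfTI volumes (`<stem>_real.nii.gz`,
#' `<stem>_imag.nii.gz`) plus a JSON sidecar (`<stem>.json`) recording the
#' grid size and, for [add_noise_for_target_snr()] results, the noise sigma,
#' target SNR and seed.
#'
#' @param kspace complex matrix or `kspace_sample`.
#' @param stem output path stem (no extension).
#' @return the sidecar path, invisibly.
#' @export
write_kspace <- function(kspace, stem) {
  meta <- list(n = nrow(kspace_data(kspace)))
  if (inherits(kspace, "kspace_sample"))
    meta <- c(meta, list(noise_sigma = kspace$noise_sigma,
                         target_snr = kspace$target_snr, seed = kspace$seed))
  y <- kspace_data(kspace)
  RNifti::writeNifti(RNifti::asNifti(Re(y)), paste0(stem, "_real.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(y)), paste0(stem, "_imag.nii.gz"))
  sidecar <- paste0(stem, ".json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"), sidecar)
  invisible(sidecar)
}

#' Load complex k-space saved by [write_kspace()]
#'
#' @param stem the path stem used when saving.
#' @return a `kspace_sample`.
#' @export
read_kspace <- function(stem) {
  re <- read_image_nifti(paste0(stem, "_real.nii.gz"))
  im <- read_image_nifti(paste0(stem, "_imag.nii.gz"))
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  structure(list(data = matrix(complex(real = re, imaginary = im),
                               nrow(re), ncol(re)),
                 n = meta$n,
                 noise_sigma = meta$noise_sigma %||% 0,
                 target_snr = meta$target_snr %||% Inf,
                 seed = meta$seed %||% NA_integer_),
            class = "kspace_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a run configuration as YAML
#'
#' Serializes an [experiment_config()] (including the nested
#' [zs_ssl_config()]) to YAML and back.
#'
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @return `path` invisibly, or the restored `experiment_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  lst <- unclass(config)
  lst$zs <- unclass(lst$zs)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  zs <- do.call(zs_ssl_config, lst$zs[setdiff(names(lst$zs), "kernel")])
  lst$zs <- NULL
  do.call(experiment_config, c(lst, list(zs = zs)))
}
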