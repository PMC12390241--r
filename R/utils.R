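# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of a cell label, used to derive per-cell seeds.
cell_seed <- function(base_seed, ...) {
  lab <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "|")
  h <- 0
  for (b in utf8ToInt(lab)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

#' Rectangular pixel region of interest
#'
#' A lightweight container for an axis-aligned pixel box, used for SNR
#' measurement regions and blur-fit windows.
#'
#' @param rows,cols integer ranges (any integer vectors; stored as their
#'   full `min:max` span).
#' @return an object of class `pixel_roi` with elements `rows` and `cols`.
#' @export
roi <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) == 0 || length(cols) == 0) stop("empty ROI")
  structure(list(rows = min(rows):max(rows), cols = min(cols):max(cols)),
            class = "pixel_roi")
}

#' @export
print.pixel_roi <- function(x, ...) {
  cat(sprintf("<pixel_roi> rows %d..%d, cols %d..%d\n",
              min(x$rows), max(x$rows), min(x$cols), max(x$cols)))
  invisible(x)
}

#' Extract the pixels of an image covered by a ROI
#'
#' @param image a matrix.
#' @param r a [roi()].
#' @return the sub-matrix `image[r$rows, r$cols]`.
#' @export
roi_pixels <- function(image, r) {
  stopifnot(inherits(r, "pixel_roi"))
  if (max(r$rows) > nrow(image) || max(r$cols) > ncol(image) ||
      min(r$rows) < 1 || min(r$cols) < 1)
    stop("ROI exceeds image bounds")
  image[r$rows, r$cols, drop = FALSE]
}

#' Normalized root-mean-square error
#'
#' `||x - ref|| / ||ref||` over all pixels, computed on magnitudes if either
#' input is complex.
#'
#' @param x,ref same-sized matrices (real or complex).
#' @return a single number.
#' @export
nrmse <- function(x, ref) {
  if (!all(dim(x) == dim(ref))) stop("shape mismatch")
  if (is.complex(x)) x <- Mod(x)
  if (is.complex(ref)) ref <- Mod(ref)
  sqrt(sum((x - ref)^2)) / sqrt(sum(ref^2))
}

# 2-D integral image box sums: S[i, j] = sum of x[1:i, 1:j]
integral_image <- function(x) {
  apply(apply(x, 2, cumsum), 1, cumsum) |> t()
}

# Sum of x over rows r0:r1, cols c0:c1 given its integral image.
box_sum <- function(S, r0, r1, c0, c1) {
  S[r1, c1] -
    (if (r0 > 1) S[r0 - 1, c1] else 0) -
    (if (c0 > 1) S[r1, c0 - 1] else 0) +
    (if (r0 > 1 && c0 > 1) S[r0 - 1, c0 - 1] else 0)
}

as_complex_matrix <- function(x) {
  if (is.complex(x)) return(x)
  matrix(complex(real = x, imaginary = 0), nrow(x), ncol(x))
}

check_square <- function(x, what = "input") {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(sprintf("%s must be a square matrix", what))
  invisible(x)
}
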