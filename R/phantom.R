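# Numerical phantom: solution-filled medium (intensity 1) with embedded
# signal-free structures, rasterized on a supersampled grid and block-averaged
# down so edge pixels carry partial-volume values.

#' Structure specification
#'
#' @param shape `"circle"` or `"square"`.
#' @param size structure size in pixels of the final grid: circle diameter or
#'   square side. May be fractional.
#' @param center numeric `(row, col)` center in continuous pixel coordinates
#'   (pixel `i` spans `[i-1, i]`, so its center is `i - 0.5`).
#' @param label optional identifier; defaults to `"<shape>_<size>"`.
#' @return an object of class `structure_spec`.
#' @export
structure_spec <- function(shape = c("circle", "square"), size, center,
                           label = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(size) || length(size) != 1 || size <= 0)
    stop("size must be a positive number")
  if (!is.numeric(center) || length(center) != 2)
    stop("center must be (row, col)")
  if (is.null(label)) label <- paste0(shape, "_", format(size))
  structure(list(shape = shape, size = size, center = as.numeric(center),
                 label = label),
            class = "structure_spec")
}

# circumscribed radius, used for conservative gap/bounds checks
struct_radius <- function(s) {
  if (s$shape == "circle") s$size / 2 else s$size * sqrt(2) / 2
}

#' Default phantom layout
#'
#' Nine structures — circles of diameter 2, 4, 6, 8, 10, 20, 30 and 40 pixels
#' and one square of side 50 pixels at `n = 512` — placed on a deterministic
#' 3x3 grid inside a centered solution disk occupying 70% of the field of
#' view. For other image sizes every length scales by `n/512`, so the layout
#' is a geometric miniature of the 512-pixel reference; labels keep the
#' 512-pixel names (e.g. `"circle_20"`).
#'
#' @param n image side in pixels.
#' @return list of [structure_spec()] objects.
#' @export
paper_default_structures <- function(n = 512) {
  sc <- n / 512
  ctr <- n / 2
  d <- 96 * sc
  sizes <- c(2, 4, 6, 8, 10, 20, 30, 40)
  # corners: four smallest; edge midpoints: 10..40; center: the square
  pos <- list(
    circle_2  = c(ctr + d, ctr + d),
    circle_4  = c(ctr + d, ctr - d),
    circle_6  = c(ctr - d, ctr + d),
    circle_8  = c(ctr - d, ctr - d),
    circle_10 = c(ctr + d, ctr),
    circle_20 = c(ctr - d, ctr),
    circle_30 = c(ctr, ctr + d),
    circle_40 = c(ctr, ctr - d)
  )
  out <- lapply(seq_along(sizes), function(i) {
    lab <- paste0("circle_", sizes[i])
    structure_spec("circle", sizes[i] * sc, pos[[lab]], label = lab)
  })
  c(out, list(structure_spec("square", 50 * sc, c(ctr, ctr),
                             label = "square_50")))
}

default_solution <- function(n) {
  list(shape = "circle", size = 0.7 * n, center = c(n / 2, n / 2))
}

# logical inside-test for continuous points (xr, xc); ties count as inside
inside_shape <- function(shape, size, center, xr, xc) {
  if (shape == "circle") {
    (xr - center[1])^2 + (xc - center[2])^2 <= (size / 2)^2
  } else {
    (abs(xr - center[1]) <= size / 2) & (abs(xc - center[2]) <= size / 2)
  }
}

check_geometry <- function(structures, solution, n) {
  for (s in structures) {
    r <- struct_radius(s)
    if (s$center[1] - r < 2 || s$center[1] + r > n - 2 ||
        s$center[2] - r < 2 || s$center[2] + r > n - 2)
      stop(sprintf("structure '%s' violates the 2-px image margin", s$label))
  }
  if (length(structures) >= 2) {
    for (i in seq_len(length(structures) - 1)) {
      for (j in (i + 1):length(structures)) {
        si <- structures[[i]]; sj <- structures[[j]]
        gap <- sqrt(sum((si$center - sj$center)^2)) -
          struct_radius(si) - struct_radius(sj)
        if (gap < 4)
          stop(sprintf("structures '%s' and '%s' are closer than the 4-px gap",
                       si$label, sj$label))
      }
    }
  }
  invisible(TRUE)
}

# mean over s x s blocks; V is (n*s) x (n*s)
block_mean <- function(V, s) {
  if (s == 1) return(V)
  n <- nrow(V) %/% s
  A <- matrix(colMeans(matrix(V, nrow = s)), nrow = n)      # n x (n*s)
  t(matrix(colMeans(matrix(t(A), nrow = s)), nrow = n))     # n x n
}

#' Generate the numerical phantom
#'
#' Rasterizes the solution region and embedded structures on a grid
#' supersampled by `supersample` along each axis (a supersampled pixel belongs
#' to a shape iff its center lies inside it, ties inside), then block-averages
#' down to `n x n`, so edge pixels carry partial-volume values in `[0, 1]`.
#' The solution has intensity 1; structure interiors and the exterior
#' background are 0.
#'
#' @param n final image side in pixels (>= 64).
#' @param supersample integer supersampling factor (>= 1); the reference
#'   512-pixel phantom uses 8, i.e. an intermediate 4096 x 4096 raster.
#' @param structures list of [structure_spec()], or `"paper-default"` for the
#'   [paper_default_structures()] layout.
#' @param solution solution-region geometry as
#'   `list(shape =, size =, center =)`; default: centered disk with diameter
#'   `0.7 n`.
#' @param roi_side side of the automatically placed SNR ROIs
#'   (see [default_rois()]); default `max(8, round(32 * n / 512))`.
#' @return an object of class `mrm_phantom`: list with `image` (the ideal
#'   image W), `n`, `supersample`, `structures`, `solution`, `signal_roi`,
#'   `background_roi`.
#' @export
generate_phantom <- function(n = 512, supersample = 8,
                             structures = "paper-default",
                             solution = NULL,
                             roi_side = NULL) {
  if (n < 64) stop("n must be >= 64")
  if (supersample < 1 || supersample != round(supersample))
    stop("supersample must be a positive integer")
  if (identical(structures, "paper-default"))
    structures <- paper_default_structures(n)
  if (inherits(structures, "structure_spec")) structures <- list(structures)
  if (is.null(solution)) solution <- default_solution(n)
  check_geometry(structures, solution, n)

  ns <- n * supersample
  cc <- (seq_len(ns) - 0.5) / supersample  # supersampled pixel centers
  # solution region
  if (solution$shape == "circle") {
    dr2 <- (cc - solution$center[1])^2
    dc2 <- (cc - solution$center[2])^2
    V <- outer(dr2, dc2, `+`) <= (solution$size / 2)^2
  } else {
    V <- outer(abs(cc - solution$center[1]) <= solution$size / 2,
               abs(cc - solution$center[2]) <= solution$size / 2, `&`)
  }
  V <- V * 1
  # carve out structures within their bounding boxes
  for (s in structures) {
    r <- s$size / 2 + 2 / supersample
    ri <- which(cc >= s$center[1] - r & cc <= s$center[1] + r)
    ci <- which(cc >= s$center[2] - r & cc <= s$center[2] + r)
    if (!length(ri) || !length(ci)) next
    ins <- outer(cc[ri], cc[ci],
                 function(a, b) inside_shape(s$shape, s$size, s$center, a, b))
    V[ri, ci][ins] <- 0
  }
  img <- block_mean(V, supersample)

  ph <- structure(list(image = img, n = n, supersample = supersample,
                       structures = structures, solution = solution,
                       signal_roi = NULL, background_roi = NULL),
                  class = "mrm_phantom")
  if (is.null(roi_side)) roi_side <- max(8, round(32 * n / 512))
  rois <- default_rois(ph, roi_side)
  ph$signal_roi <- rois$signal_roi
  ph$background_roi <- rois$background_roi
  ph
}

#' @export
print.mrm_phantom <- function(x, ...) {
  cat(sprintf("<mrm_phantom> %d x %d (supersample %d), %d structures\n",
              x$n, x$n, x$supersample, length(x$structures)))
  cat("  structures:", paste(vapply(x$structures, `[[`, "", "label"),
                             collapse = ", "), "\n")
  invisible(x)
}

# candidate search shared by both ROIs: valid(r0, c0, side) must be cheap
best_box <- function(n, side, valid, stride = 2) {
  starts <- seq(1, n - side + 1, by = stride)
  best <- NULL; best_m <- -1
  max_m <- (n - side) %/% 2
  for (r0 in starts) {
    for (c0 in starts) {
      if (!valid(r0, c0, side)) next
      # largest margin m such that the box inflated by m stays valid
      lo <- 0; hi <- max_m
      while (lo < hi) {
        mid <- (lo + hi + 1) %/% 2
        ok <- r0 - mid >= 1 && c0 - mid >= 1 &&
          r0 + side - 1 + mid <= n && c0 + side - 1 + mid <= n &&
          valid(r0 - mid, c0 - mid, side + 2 * mid)
        if (ok) lo <- mid else hi <- mid - 1
      }
      if (lo > best_m) {
        best_m <- lo
        best <- c(r0, c0)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(roi = roi(best[1]:(best[1] + side - 1), best[2]:(best[2] + side - 1)),
       margin = best_m)
}

#' Default SNR measurement ROIs
#'
#' Places one `roi_side x roi_side` box fully inside the solution region
#' (every noise-free pixel exactly 1) and one fully inside the exterior
#' background (every pixel exactly 0 and outside the solution), each chosen to
#' be maximally distant from structure and solution edges.
#'
#' @param phantom an [generate_phantom()] result.
#' @param roi_side ROI side in pixels (>= 8).
#' @return `list(signal_roi =, background_roi =)` of [roi()] objects.
#' @export
default_rois <- function(phantom, roi_side = 32) {
  stopifnot(inherits(phantom, "mrm_phantom"))
  if (roi_side < 8) stop("roi_side must be >= 8")
  n <- phantom$n
  img <- phantom$image
  Ssig <- integral_image((img == 1) * 1)
  # exterior background: zero pixels outside the solution region
  ctr <- (seq_len(n)) - 0.5
  sol <- phantom$solution
  out_sol <- !outer(ctr, ctr, function(a, b)
    inside_shape(sol$shape, sol$size + 2, sol$center, a, b))
  Sbg <- integral_image(((img == 0) & out_sol) * 1)

  valid_sig <- function(r0, c0, side)
    box_sum(Ssig, r0, r0 + side - 1, c0, c0 + side - 1) == side^2
  valid_bg <- function(r0, c0, side)
    box_sum(Sbg, r0, r0 + side - 1, c0, c0 + side - 1) == side^2

  stride <- max(2, n %/% 128)
  sig <- best_box(n, roi_side, valid_sig, stride)
  bg <- best_box(n, roi_side, valid_bg, stride)
  if (is.null(sig))
    stop("no valid signal ROI placement of side ", roi_side)
  if (is.null(bg))
    stop("no valid background ROI placement of side ", roi_side)
  list(signal_roi = sig$roi, background_roi = bg$roi)
}

#' Blur-fit window around a structure
#'
#' Square window of side `max(16, 2 * structure size)` centered on the named
#' structure, clipped to the image.
#'
#' @param phantom an `mrm_phantom`.
#' @param label a structure label (e.g. `"circle_20"`).
#' @return a [roi()].
#' @export
structure_window <- function(phantom, label) {
  labs <- vapply(phantom$structures, `[[`, "", "label")
  i <- match(label, labs)
  if (is.na(i)) stop("unknown structure label: ", label)
  s <- phantom$structures[[i]]
  side <- max(16, round(2 * s$size))
  r0 <- max(1, round(s$center[1] - side / 2))
  c0 <- max(1, round(s$center[2] - side / 2))
  r1 <- min(phantom$n, r0 + side - 1)
  c1 <- min(phantom$n, c0 + side - 1)
  roi(r0:r1, c0:c1)
}
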