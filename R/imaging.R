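# Downstream operations on loaded spectra: chromatogram extraction,
# m/z-window ion-image slicing, TrIQ contrast quantization and palettes.

#' Base-peak chromatogram
#'
#' Per-spectrum maximum intensity, in spectrum order.  Empty spectra
#' contribute 0.
#'
#' @param spectra an `ms_spectra` object or a list of spectra, each with an
#'   `intensity` vector.
#' @return numeric vector, one value per spectrum.
#' @examples
#' sp <- random_spectra(5, c(10, 20), seed = 1)
#' bpc(sp)
#' @export
bpc <- function(spectra) {
  vapply(spectra, function(sp) {
    if (length(sp$intensity) == 0) 0 else max(sp$intensity)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Total ion current
#'
#' Per-spectrum summed intensity, in spectrum order.  Empty spectra
#' contribute 0.
#'
#' @inheritParams bpc
#' @return numeric vector, one value per spectrum.
#' @export
tic <- function(spectra) {
  vapply(spectra, function(sp) sum(sp$intensity), numeric(1),
         USE.NAMES = FALSE)
}

#' Extract an ion image for an m/z window
#'
#' For every stored pixel, aggregates the intensities whose m/z lies in the
#' closed interval `[target_mz - tol, target_mz + tol]` and places the result
#' at grid cell (row = y, column = x).  Grid cells without a stored pixel are
#' 0.
#'
#' @param pixels an `ms_pixels` object from [read_imzml()], or a plain list
#'   of pixels (each with `x`, `y`, `mz`, `intensity`), in which case `dims`
#'   must be given.
#' @param target_mz window center (m/z).
#' @param tol half-window width (m/z), must be positive.
#' @param dims an `ms_image_dims` (or `c(max_x, max_y)`) when `pixels` is a
#'   plain list.
#' @param agg aggregate within the window by `"sum"` (default; robust to
#'   centroids split across the narrow window) or `"max"`.
#' @return an `ms_ion_image`: list with `values` (max_y x max_x matrix),
#'   `target_mz` and `tol`.
#' @examples
#' px <- random_pixels(4, 3, len_range = c(5, 10), seed = 7)
#' img <- get_slice(px, target_mz = 500, tol = 100, dims = c(4, 3))
#' dim(img$values)
#' @export
get_slice <- function(pixels, target_mz, tol, dims = NULL,
                      agg = c("sum", "max")) {
  agg <- match.arg(agg)
  if (!is.numeric(tol) || length(tol) != 1 || !is.finite(tol) || tol <= 0)
    msio_stop("parameter", "'tol' must be a positive m/z half-window")
  if (inherits(pixels, "ms_pixels")) {
    if (is.null(dims)) dims <- pixels$dims
    pixels <- pixels$pixels
  }
  if (is.null(dims))
    msio_stop("parameter", "'dims' is required when 'pixels' is a plain list")
  if (!inherits(dims, "ms_image_dims"))
    dims <- new_image_dims(dims[[1]], dims[[2]],
                           if (length(dims) >= 3) dims[[3]] else length(pixels))

  lo <- target_mz - tol
  hi <- target_mz + tol
  values <- matrix(0, nrow = dims$max_y, ncol = dims$max_x)
  for (i in seq_along(pixels)) {
    p <- pixels[[i]]
    if (p$x < 1 || p$x > dims$max_x || p$y < 1 || p$y > dims$max_y)
      msio_stop("out_of_grid",
                sprintf("pixel %d at (%d, %d) lies outside the %d x %d grid",
                        i, p$x, p$y, dims$max_x, dims$max_y))
    sel <- p$mz >= lo & p$mz <= hi
    if (any(sel)) {
      v <- if (agg == "sum") sum(p$intensity[sel]) else max(p$intensity[sel])
      values[p$y, p$x] <- if (agg == "sum") values[p$y, p$x] + v
                          else max(values[p$y, p$x], v)
    }
  }
  structure(list(values = values, target_mz = target_mz, tol = tol),
            class = "ms_ion_image")
}

#' @export
print.ms_ion_image <- function(x, ...) {
  cat(sprintf("<ms_ion_image> %d x %d, m/z %.4f +/- %.4f, max %.4g\n",
              ncol(x$values), nrow(x$values), x$target_mz, x$tol,
              max(x$values)))
  invisible(x)
}

#' Threshold Intensity Quantization (TrIQ)
#'
#' Contrast optimization for ion images: intensities are capped at the
#' smallest observed value `T` whose empirical cumulative probability reaches
#' `p`, then linearly quantized to `L` levels:
#' `level(v) = floor((min(v, T) - v_min) / (T - v_min) * (L - 1))`.
#' Outliers above `T` map to the top level instead of compressing the scale
#' of the remaining pixels.  The threshold uses the exact empirical
#' distribution (sorted values), not a binned histogram.
#'
#' @param image an `ms_ion_image` or a numeric matrix.
#' @param L number of quantization levels (at least 2).
#' @param p target cumulative probability in (0, 1].
#' @return an `ms_triq` object: `levels` (integer matrix in `[0, L-1]`),
#'   `L`, `p` and the selected intensity `threshold`.
#' @examples
#' q <- triq(matrix(c(0:7, 100), 3, 3), L = 256, p = 0.95)
#' q$threshold
#' @export
triq <- function(image, L = 256L, p = 0.95) {
  values <- if (inherits(image, "ms_ion_image")) image$values else image
  if (!is.matrix(values) || !is.numeric(values))
    msio_stop("parameter", "'image' must be a numeric matrix or ms_ion_image")
  if (!is.numeric(L) || length(L) != 1 || L < 2)
    msio_stop("parameter", "'L' must be at least 2")
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    msio_stop("parameter", "'p' must lie in (0, 1]")
  L <- as.integer(L)

  v <- as.vector(values)
  n <- length(v)
  v_min <- min(v)
  sorted <- sort(v)
  threshold <- sorted[ceiling(p * n)]

  if (threshold == v_min) {
    lev <- matrix(0L, nrow = nrow(values), ncol = ncol(values))
  } else {
    clipped <- pmin(values, threshold)
    lev <- floor((clipped - v_min) / (threshold - v_min) * (L - 1))
    lev <- matrix(as.integer(pmin(lev, L - 1L)), nrow = nrow(values))
  }
  structure(list(levels = lev, L = L, p = p, threshold = threshold),
            class = "ms_triq")
}

#' @export
print.ms_triq <- function(x, ...) {
  cat(sprintf("<ms_triq> %d x %d, %d levels, p = %g, threshold = %.6g\n",
              ncol(x$levels), nrow(x$levels), x$L, x$p, x$threshold))
  invisible(x)
}

#' The 256-entry viridis palette
#'
#' The standard perceptually uniform viridis color map, as 256 RGB triples
#' with 0-255 channels.  Entry 1 is dark purple (68, 1, 84); entry 256 is
#' yellow (253, 231, 37).
#'
#' @return an integer matrix of 256 rows and columns `red`, `green`, `blue`.
#' @export
viridis_palette <- function() {
  t(grDevices::col2rgb(viridisLite::viridis(256)))
}
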