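#' Lattice patterns of per-site state vectors
#'
#' A `grid_pattern` is the universal input of every measure in this package:
#' a 2D raster or 3D voxel field whose sites carry one or more numeric bands
#' (e.g. the three channels of a color photograph, or a single occupancy
#' value for a lattice gas). Bands are stored as a list of arrays sharing the
#' same spatial shape; `value_range` records the admissible `[lo, hi]` per
#' band, which the configurational-entropy measures use as the microstate
#' bounds.
#'
#' @param values a numeric array (matrix for 2D, 3-way array for 3D) holding
#'   a single band, or a list of such arrays for a multi-band pattern.
#' @param value_range a length-2 numeric vector `c(lo, hi)` applied to every
#'   band, or an `n_bands x 2` matrix. Defaults to the observed min/max per
#'   band.
#' @param band_names optional character labels, one per band.
#'
#' @return an object of class `grid_pattern` with elements `bands` (list of
#'   arrays), `value_range` (`n_bands x 2` matrix), `band_names`.
#' @examples
#' p <- grid_pattern(matrix(0:3, 2, 2))
#' grid_shape(p)
#' @export
grid_pattern <- function(values, value_range = NULL, band_names = NULL) {
  if (!is.list(values)) values <- list(values)
  values <- lapply(values, function(v) {
    if (is.null(dim(v))) stop("band values must be a matrix or array", call. = FALSE)
    if (!is.numeric(v)) stop("band values must be numeric", call. = FALSE)
    v
  })
  shp <- dim(values[[1]])
  if (!length(shp) %in% c(2L, 3L))
    stop("grid_pattern supports 2D and 3D lattices only", call. = FALSE)
  if (any(shp < 1L)) stop("all spatial extents must be >= 1", call. = FALSE)
  for (v in values) {
    if (!identical(dim(v), shp))
      stop("all bands must share the same spatial shape", call. = FALSE)
  }
  nb <- length(values)
  if (is.null(value_range)) {
    value_range <- t(vapply(values, function(v) range(v, finite = TRUE), numeric(2)))
  } else {
    if (is.vector(value_range)) value_range <- matrix(value_range, nb, 2, byrow = TRUE)
    value_range <- as.matrix(value_range)
    if (!identical(dim(value_range), c(nb, 2L)))
      stop("value_range must be c(lo, hi) or an n_bands x 2 matrix", call. = FALSE)
  }
  if (any(value_range[, 1] > value_range[, 2]))
    stop("value_range must satisfy lo <= hi", call. = FALSE)
  for (b in seq_len(nb)) {
    v <- values[[b]]
    if (any(!is.finite(v))) stop("pattern values must be finite", call. = FALSE)
    if (any(v < value_range[b, 1] - 1e-9) || any(v > value_range[b, 2] + 1e-9))
      stop("pattern values fall outside the declared value_range", call. = FALSE)
  }
  if (!is.null(band_names) && length(band_names) != nb)
    stop("band_names must have one entry per band", call. = FALSE)
  structure(
    list(bands = values, value_range = value_range, band_names = band_names),
    class = "grid_pattern"
  )
}

#' @export
print.grid_pattern <- function(x, ...) {
  shp <- grid_shape(x)
  cat(sprintf(
    "<grid_pattern> %s lattice, %d band(s), shape %s\n",
    paste0(grid_dim(x), "D"), n_bands(x), paste(shp, collapse = " x ")
  ))
  for (b in seq_len(n_bands(x))) {
    nm <- if (is.null(x$band_names)) sprintf("band %d", b) else x$band_names[b]
    cat(sprintf("  %s: range [%g, %g]\n", nm, x$value_range[b, 1], x$value_range[b, 2]))
  }
  invisible(x)
}

#' @rdname grid_pattern
#' @param x a `grid_pattern`.
#' @export
grid_shape <- function(x) dim(x$bands[[1]])

#' @rdname grid_pattern
#' @export
grid_dim <- function(x) length(dim(x$bands[[1]]))

#' @rdname grid_pattern
#' @export
n_bands <- function(x) length(x$bands)

#' @rdname grid_pattern
#' @export
is_grid_pattern <- function(x) inherits(x, "grid_pattern")

#' Test whether every site value is a whole number
#'
#' The microstate-counting entropies are defined on integer gradients;
#' decimal-valued patterns must first pass through [quantize()].
#'
#' @param x a `grid_pattern`.
#' @param tol absolute tolerance for whole-number comparison.
#' @return `TRUE` if all values in all bands are integers (up to `tol`).
#' @export
is_integer_quantized <- function(x, tol = 1e-9) {
  all(vapply(x$bands, function(v) all(abs(v - round(v)) <= tol), logical(1)))
}

#' Round half away from zero towards +Inf
#'
#' Fixed "half-up" convention used everywhere rounding appears in this
#' package (quantization, size-preserving entropy hierarchies), so that
#' results do not depend on R's default round-half-to-even.
#'
#' @param x numeric.
#' @return `floor(x + 0.5)`.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Quantize a decimal-valued pattern to integers
#'
#' Scales every site value (and the declared value range) by an integer
#' multiplier and rounds half-up. Decimal gradients — for instance spin
#' textures with components in `[-1, 1]` at a precision of 1e-6 — become
#' integer gradients on which microstate counting is well defined; a
#' multiplier of 1e6 turns a precision-1e-6 value such as 0.000001 into 1.
#'
#' @param pattern a `grid_pattern`.
#' @param multiplier integer scale factor, >= 1.
#' @return an integer-quantized `grid_pattern` with scaled `value_range`.
#' @examples
#' p <- grid_pattern(matrix(c(-0.5, 0, 0.5, 1), 2, 2), value_range = c(-1, 1))
#' quantize(p, 10)$value_range
#' @export
quantize <- function(pattern, multiplier = 1L) {
  stopifnot(is_grid_pattern(pattern))
  if (!is.finite(multiplier) || multiplier < 1 || multiplier != round(multiplier))
    stop("multiplier must be an integer >= 1", call. = FALSE)
  bands <- lapply(pattern$bands, function(v) {
    if (any(!is.finite(v))) stop("cannot quantize non-finite values", call. = FALSE)
    out <- round_half_up(v * multiplier)
    dim(out) <- dim(v)
    out
  })
  vr <- pattern$value_range * multiplier
  vr[, 1] <- floor(vr[, 1]); vr[, 2] <- ceiling(vr[, 2])
  grid_pattern(bands, value_range = vr, band_names = pattern$band_names)
}
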