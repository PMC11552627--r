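#' Observation transforms: how a system is seen
#'
#' A 3D system can be observed *stereoscopically* (the full voxel field),
#' *laterally* (summing voxels along the depth axis into one image), or
#' *cross-sectionally* (a single slice); each observation can additionally be
#' coarsened to a lower resolution. The dimension and resolution of the
#' observation — not just the system itself — determine the measured
#' complexity, which is the central phenomenon this package quantifies.
#'
#' @name observe
NULL

# Sum (or mean) each factor^D block of an array, shrinking it. Workhorse
# behind coarsening, projection bookkeeping and renormalization.
block_reduce <- function(a, factor, op = c("sum", "mean")) {
  op <- match.arg(op)
  d <- dim(a)
  if (factor == 1L) return(a)
  if (any(d %% factor != 0))
    stop("factor ", factor, " does not divide shape ", paste(d, collapse = "x"),
         call. = FALSE)
  nd <- length(d)
  newd <- d %/% factor
  if (nd == 2L) {
    dim(a) <- c(factor, newd[1], factor, newd[2])
    out <- colSums(aperm(a, c(1, 3, 2, 4)), dims = 2)
  } else {
    dim(a) <- c(factor, newd[1], factor, newd[2], factor, newd[3])
    out <- colSums(aperm(a, c(1, 3, 5, 2, 4, 6)), dims = 3)
  }
  dim(out) <- newd
  if (op == "mean") out <- out / factor^nd
  out
}

# Replicate each cell of a reduced array back onto a factor-times-finer
# lattice (inverse bookkeeping of block_reduce).
block_replicate <- function(a, factor) {
  if (factor == 1L) return(a)
  d <- dim(a)
  if (length(d) == 2L) {
    a[rep(seq_len(d[1]), each = factor), rep(seq_len(d[2]), each = factor)]
  } else {
    a[rep(seq_len(d[1]), each = factor), rep(seq_len(d[2]), each = factor),
      rep(seq_len(d[3]), each = factor)]
  }
}

#' Split or merge the bands of a 2D pattern
#'
#' Multi-band measures in this package follow the convention that the
#' measure of a color image is the sum of the per-band measures. This
#' helper exposes the three band strategies used for color photographs:
#' `"per_band_sum"` returns each band as its own single-band pattern (the
#' caller sums the measures), `"grayscale"` collapses an RGB image to one
#' luma band (ITU-R BT.601: 0.299 R + 0.587 G + 0.114 B, rounded half-up),
#' and `"single_band"` selects one band.
#'
#' @param pattern a 2D [grid_pattern()].
#' @param strategy one of `"per_band_sum"`, `"grayscale"`, `"single_band"`.
#' @param band band index for `"single_band"` (1-based).
#' @return a list of single-band `grid_pattern`s (length 3 for
#'   `per_band_sum` on RGB, otherwise length 1). Values are never altered,
#'   only selected or combined.
#' @export
apply_band_strategy <- function(pattern,
                                strategy = c("per_band_sum", "grayscale", "single_band"),
                                band = 1L) {
  stopifnot(is_grid_pattern(pattern))
  strategy <- match.arg(strategy)
  if (grid_dim(pattern) != 2L)
    stop("band strategies apply to 2D patterns", call. = FALSE)
  one <- function(b, name = NULL) {
    grid_pattern(pattern$bands[[b]], value_range = pattern$value_range[b, ],
                 band_names = name)
  }
  switch(strategy,
    per_band_sum = lapply(seq_len(n_bands(pattern)), one),
    single_band = {
      if (band < 1L || band > n_bands(pattern))
        stop("band index out of range", call. = FALSE)
      list(one(band))
    },
    grayscale = {
      if (n_bands(pattern) != 3L)
        stop("grayscale conversion requires a 3-band (RGB) pattern", call. = FALSE)
      w <- c(0.299, 0.587, 0.114)
      luma <- round_half_up(w[1] * pattern$bands[[1]] + w[2] * pattern$bands[[2]] +
                              w[3] * pattern$bands[[3]])
      vr <- c(round_half_up(sum(w * pattern$value_range[, 1])),
              round_half_up(sum(w * pattern$value_range[, 2])))
      list(grid_pattern(luma, value_range = vr, band_names = "luma"))
    }
  )
}

#' Lateral observation: sum-projection of a 3D field
#'
#' Collapses a voxel field to a 2D image by adding up the voxel values at
#' each 2D position along the depth axis — how a translucent 3D system looks
#' from the side. A binary 64-cube projects to pixel values in `0..64`.
#' The grand total of the field is conserved exactly.
#'
#' @param field a 3D single-band [grid_pattern()].
#' @param axis which axis is "depth" (default: the third).
#' @return a 2D `grid_pattern` with `value_range` `[K*lo, K*hi]`.
#' @export
lateral_projection <- function(field, axis = 3L) {
  stopifnot(is_grid_pattern(field))
  if (grid_dim(field) != 3L) stop("lateral projection requires a 3D field", call. = FALSE)
  if (n_bands(field) != 1L) stop("lateral projection requires a single band", call. = FALSE)
  v <- field$bands[[1]]
  keep <- setdiff(1:3, axis)
  img <- apply(v, keep, sum)
  K <- dim(v)[axis]
  grid_pattern(img, value_range = K * field$value_range[1, ])
}

#' Cross-sectional observation: a single layer of a 3D field
#'
#' Extracts one 2D slice along the depth axis, values untouched. Layer
#' indices are 1-based ("the 32nd layer" is `layer_index = 32`).
#'
#' @param field a 3D single-band [grid_pattern()].
#' @param layer_index 1-based index along `axis`.
#' @param axis slicing axis (default: the third).
#' @return a 2D `grid_pattern` with the field's `value_range`.
#' @export
cross_section <- function(field, layer_index, axis = 3L) {
  stopifnot(is_grid_pattern(field))
  if (grid_dim(field) != 3L) stop("cross-section requires a 3D field", call. = FALSE)
  if (n_bands(field) != 1L) stop("cross-section requires a single band", call. = FALSE)
  v <- field$bands[[1]]
  K <- dim(v)[axis]
  if (layer_index < 1L || layer_index > K)
    stop("layer_index ", layer_index, " out of bounds (1..", K, ")", call. = FALSE)
  img <- switch(axis,
    v[layer_index, , ],
    v[, layer_index, ],
    v[, , layer_index]
  )
  grid_pattern(img, value_range = field$value_range[1, ])
}

#' Coarsen the observation resolution
#'
#' Replaces each `factor^D` block by a single cell holding the block sum:
#' a coarser observation unit reflects the aggregated property of the local
#' values it can no longer resolve. The grand total is conserved exactly;
#' `value_range` scales by `factor^D`. A mean-valued variant exists for
#' convenience but sum is the default aggregation.
#'
#' @param pattern a single-band 2D or 3D [grid_pattern()].
#' @param factor integer >= 1 dividing every spatial extent.
#' @param op `"sum"` (default) or `"mean"`.
#' @return the coarsened `grid_pattern`.
#' @export
coarsen <- function(pattern, factor, op = c("sum", "mean")) {
  stopifnot(is_grid_pattern(pattern))
  op <- match.arg(op)
  if (n_bands(pattern) != 1L) stop("coarsen requires a single band", call. = FALSE)
  if (factor < 1L || factor != round(factor))
    stop("factor must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(pattern)
  v <- block_reduce(pattern$bands[[1]], as.integer(factor), op = op)
  scale <- if (op == "sum") factor^grid_dim(pattern) else 1
  grid_pattern(v, value_range = scale * pattern$value_range[1, ])
}

#' Apply a full observation specification to a 3D field
#'
#' Convenience wrapper combining the dimension of observation
#' (`"stereoscopic"`, `"lateral"`, `"cross_section"`) with optional
#' resolution coarsening.
#'
#' @param field a 3D single-band [grid_pattern()].
#' @param mode observation mode.
#' @param layer_index layer for `"cross_section"` (1-based).
#' @param coarsen_factor integer >= 1.
#' @param axis depth axis for projection/slicing.
#' @return a `grid_pattern` (2D for lateral/cross-section, 3D for
#'   stereoscopic).
#' @export
observe <- function(field, mode = c("stereoscopic", "lateral", "cross_section"),
                    layer_index = NULL, coarsen_factor = 1L, axis = 3L) {
  mode <- match.arg(mode)
  out <- switch(mode,
    stereoscopic = field,
    lateral = lateral_projection(field, axis = axis),
    cross_section = {
      if (is.null(layer_index))
        stop("cross_section observation needs layer_index", call. = FALSE)
      cross_section(field, layer_index, axis = axis)
    }
  )
  coarsen(out, coarsen_factor)
}
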