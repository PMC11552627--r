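#' Lossy-compression complexity index (ICRMSE)
#'
#' Measures image complexity by how badly a lossy codec degrades the image
#' relative to how well it shrinks it:
#' `ICRMSE(q) = RMSE(q) / CR(q)`,
#' where `RMSE(q)` is the root mean square error (in gray levels) between
#' the original and its JPEG round-trip at quality factor `q`, and
#' `CR(q) = S(I) / S(C(I))` is the compression ratio — uncompressed size
#' over compressed size. "Uncompressed size" is read literally as the raw
#' bitmap byte count (`H x W` bytes for 8-bit grayscale), not a container
#' size. Flat images compress perfectly with zero error (ICRMSE = 0); noisy
#' ones compress badly and lossily (large ICRMSE). Absolute values depend
#' on the codec build, so comparisons should stay within one platform.
#'
#' Color patterns are first collapsed to luma ([apply_band_strategy()]);
#' non-image numeric data are mapped linearly onto the integer range
#' `0..255` (by default over the pattern's own `value_range`; pass
#' `rescale_range` to fix the map across a sequence).
#'
#' @param pattern a 2D [grid_pattern()].
#' @param q JPEG quality factor, integer 1-100 (default 75).
#' @param rescale_range optional `c(lo, hi)` used for the 0-255 mapping.
#' @return a `compression_report`: list with `q`, `rmse`, `cr`, `icrmse`,
#'   `size_uncompressed`, `size_compressed`.
#' @examples
#' icrmse(grid_pattern(matrix(128, 32, 32), value_range = c(0, 255)))$icrmse  # 0
#' @export
icrmse <- function(pattern, q = 75L, rescale_range = NULL) {
  stopifnot(is_grid_pattern(pattern))
  if (grid_dim(pattern) != 2L)
    stop("ICRMSE is defined for 2D images only", call. = FALSE)
  if (q < 1 || q > 100) stop("q must lie in 1..100", call. = FALSE)
  gray <- to_gray255(pattern, rescale_range)
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f))
  jpeg::writeJPEG(gray / 255, target = f, quality = q / 100)
  size_c <- file.info(f)$size
  back <- round(jpeg::readJPEG(f) * 255)
  if (length(dim(back)) == 3L) back <- back[, , 1]
  rmse <- sqrt(mean((gray - back)^2))
  size_u <- prod(dim(gray))  # 8-bit grayscale bitmap bytes
  cr <- size_u / size_c
  structure(
    list(q = as.integer(q), rmse = rmse, cr = cr, icrmse = rmse / cr,
         size_uncompressed = size_u, size_compressed = as.numeric(size_c)),
    class = "compression_report"
  )
}

#' @export
print.compression_report <- function(x, ...) {
  cat(sprintf("<compression_report> q = %d: RMSE = %.4g, CR = %.4g, ICRMSE = %.4g\n",
              x$q, x$rmse, x$cr, x$icrmse))
  invisible(x)
}

to_gray255 <- function(pattern, rescale_range = NULL) {
  if (n_bands(pattern) == 3L) {
    pattern <- apply_band_strategy(pattern, "grayscale")[[1]]
  } else if (n_bands(pattern) != 1L) {
    stop("ICRMSE needs a 1- or 3-band pattern", call. = FALSE)
  }
  v <- pattern$bands[[1]]
  rng <- if (!is.null(rescale_range)) rescale_range else pattern$value_range[1, ]
  if (rng[1] == 0 && rng[2] == 255 && is_integer_quantized(pattern)) {
    v
  } else if (rng[2] > rng[1]) {
    round_half_up(255 * (pmin(pmax(v, rng[1]), rng[2]) - rng[1]) / (rng[2] - rng[1]))
  } else {
    array(128, dim = dim(v))  # degenerate flat range: mid-gray
  }
}

#' ICRMSE of a sequence of images
#'
#' Applies [icrmse()] to every frame, mapping all frames to `0..255` with a
#' single min-max map computed over the whole sequence so that frames are
#' comparable.
#'
#' @param patterns list of 2D [grid_pattern()]s sharing shape.
#' @param q JPEG quality factor.
#' @param control ordered control values.
#' @return a [measure_series()] of ICRMSE values; the full per-frame reports
#'   are attached as `attr(, "reports")`.
#' @export
icrmse_series <- function(patterns, q = 75L, control = NULL) {
  check_homogeneous(patterns)
  lo <- min(vapply(patterns, function(p) min(vapply(p$bands, min, numeric(1))), numeric(1)))
  hi <- max(vapply(patterns, function(p) max(vapply(p$bands, max, numeric(1))), numeric(1)))
  reports <- lapply(patterns, icrmse, q = q, rescale_range = c(lo, hi))
  vals <- vapply(reports, `[[`, numeric(1), "icrmse")
  out <- measure_series(vals, control = control, label = "ICRMSE",
                        meta = list(measure = "icrmse", q = q, range = c(lo, hi)))
  attr(out, "reports") <- reports
  out
}
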