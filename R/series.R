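#' Ordered series of a measure along a control variable
#'
#' The common container for "measure vs control" data: complexity or entropy
#' against mixing iteration, temperature (in units of the coupling `J`), or
#' applied field. Input to the derivative, transition-detection, trend and
#' correlation tools.
#'
#' @param values numeric measure values.
#' @param control ordered (strictly increasing) control values; defaults to
#'   `seq_along(values)`.
#' @param label measure name used in printing and CSV headers.
#' @param meta named list of provenance (measure, observation, seed, ...).
#' @return a `measure_series`.
#' @export
measure_series <- function(values, control = NULL, label = "measure", meta = list()) {
  values <- as.numeric(values)
  if (is.null(control)) control <- seq_along(values)
  control <- as.numeric(control)
  if (length(control) != length(values))
    stop("control and values must have the same length", call. = FALSE)
  if (length(control) > 1L && any(diff(control) <= 0))
    stop("control values must be strictly increasing", call. = FALSE)
  structure(list(control = control, values = values, label = label, meta = meta),
            class = "measure_series")
}

#' @export
print.measure_series <- function(x, ...) {
  cat(sprintf("<measure_series> %s, %d points, control [%g, %g]\n",
              x$label, length(x$values), min(x$control), max(x$control)))
  invisible(x)
}

#' @export
as.data.frame.measure_series <- function(x, ...) {
  data.frame(control = x$control, value = x$values)
}

#' Finite-difference derivative of a series
#'
#' Central differences on interior points, one-sided differences at the two
#' ends, each divided by the local control spacing.
#'
#' @param series a [measure_series()] with at least 2 points.
#' @return a `measure_series` of derivative values on the same control grid.
#' @export
derivative_series <- function(series) {
  stopifnot(inherits(series, "measure_series"))
  v <- series$values; x <- series$control; n <- length(v)
  if (n < 2L) stop("derivative needs at least 2 points", call. = FALSE)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (x[2] - x[1])
  d[n] <- (v[n] - v[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (x[i + 1] - x[i - 1])
  }
  measure_series(d, control = x, label = paste0("d(", series$label, ")/dx"),
                 meta = series$meta)
}

# Centered moving average; windows shrink symmetrically near the ends.
smooth_values <- function(v, window) {
  n <- length(v)
  window <- max(1L, as.integer(window))
  h <- window %/% 2L
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    mean(v[(i - k):(i + k)])
  }, numeric(1))
}

#' Locate a phase transition from the steepest change of a measure
#'
#' Returns the control value at which the moving-average-smoothed absolute
#' derivative of the series is maximal — where the measure changes fastest,
#' e.g. the critical temperature of an Ising sweep. Using the *absolute*
#' derivative handles increasing and decreasing measures uniformly, and
#' makes the detection equivariant under affine rescaling of the measure.
#' Ties break toward the lower control value. A series whose smoothed
#' derivative is (numerically) constant — flat or perfectly linear — admits
#' no transition and yields `NA`.
#'
#' @param series a [measure_series()] with at least 5 points.
#' @param window moving-average window (points) applied to `|derivative|`.
#' @return a `transition_result`: list with `control` (the detected control
#'   value, `NA` if none), `index`, and the smoothed `profile`.
#' @export
detect_transition <- function(series, window = 5L) {
  stopifnot(inherits(series, "measure_series"))
  if (length(series$values) < 5L)
    stop("transition detection needs at least 5 points", call. = FALSE)
  d <- derivative_series(series)
  a <- smooth_values(abs(d$values), window)
  spread <- max(a) - min(a)
  if (spread <= 1e-12 * max(max(abs(a)), .Machine$double.eps)) {
    return(structure(list(control = NA_real_, index = NA_integer_, profile = a),
                     class = "transition_result"))
  }
  i <- which.max(a)  # first maximum = lower control on ties
  structure(list(control = series$control[i], index = i, profile = a),
            class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  if (is.na(x$control)) cat("<transition_result> no transition detected\n")
  else cat(sprintf("<transition_result> control = %g (index %d)\n", x$control, x$index))
  invisible(x)
}

#' Classify the qualitative trend of a series
#'
#' Labels a series as `upward`, `downward`, `concave_down` (rise to an
#' interior peak, then fall — the disputed shape of apparent complexity
#' during mixing), `flat`, or `irregular`. The series is moving-average
#' smoothed, then judged from the position of its global extremum and the
#' net changes on each side, with changes below `tol` (a fraction of the
#' series range, default 2%) treated as noise. A rise-to-interior-peak-and-
#' fall beyond tolerance on both sides is `concave_down`; an interior
#' trough with significant falls on both sides fits no label and is
#' `irregular`.
#'
#' @param series a [measure_series()] with at least `window` points.
#' @param window moving-average window (points).
#' @param tol tolerance as a fraction of the raw series range.
#' @return a `trend_verdict`: list with `shape`, `peak_index` (interior peak
#'   for `concave_down`, else `NA`), `smoothing_window`.
#' @export
classify_trend <- function(series, window = 5L, tol = 0.02) {
  stopifnot(inherits(series, "measure_series"))
  v <- series$values; n <- length(v)
  if (n < window) stop("series shorter than the smoothing window", call. = FALSE)
  rng <- max(v) - min(v)
  verdict <- function(shape, peak = NA_integer_)
    structure(list(shape = shape, peak_index = peak, smoothing_window = as.integer(window)),
              class = "trend_verdict")
  if (rng == 0) return(verdict("flat"))
  s <- smooth_values(v, window)
  tol_abs <- tol * rng
  if (max(s) - min(s) <= tol_abs) return(verdict("flat"))
  i_max <- which.max(s); i_min <- which.min(s)
  net <- s[n] - s[1]
  if (i_max > 1L && i_max < n &&
      s[i_max] - s[1] > tol_abs && s[i_max] - s[n] > tol_abs)
    return(verdict("concave_down", i_max))
  if (i_min > 1L && i_min < n &&
      s[1] - s[i_min] > tol_abs && s[n] - s[i_min] > tol_abs)
    return(verdict("irregular"))  # concave-up: outside the named shapes
  if (net > tol_abs) return(verdict("upward"))
  if (net < -tol_abs) return(verdict("downward"))
  verdict("irregular")
}

#' @export
print.trend_verdict <- function(x, ...) {
  cat(sprintf("<trend_verdict> %s%s (window %d)\n", x$shape,
              if (!is.na(x$peak_index)) sprintf(", peak at index %d", x$peak_index) else "",
              x$smoothing_window))
  invisible(x)
}

#' Pearson correlation between two measure series
#'
#' @param a,b [measure_series()] (or numeric vectors) of equal length >= 3.
#' @return the Pearson product-moment correlation coefficient.
#' @export
series_correlation <- function(a, b) {
  va <- if (inherits(a, "measure_series")) a$values else as.numeric(a)
  vb <- if (inherits(b, "measure_series")) b$values else as.numeric(b)
  if (length(va) != length(vb) || length(va) < 3L)
    stop("series must have equal length >= 3", call. = FALSE)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("correlation undefined for zero-variance series", call. = FALSE)
  cor(va, vb)
}
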