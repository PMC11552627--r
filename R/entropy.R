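#' Shannon entropy of the value histogram
#'
#' `ES = -sum p_v log2 p_v` over the histogram of site values: a purely
#' compositional measure of disorder, blind to the spatial arrangement of
#' the values (a checkerboard and a segregated half/half pattern score the
#' same). Multi-band patterns are measured band by band and summed.
#'
#' @param pattern an integer-quantized [grid_pattern()].
#' @return Shannon entropy in bits.
#' @examples
#' shannon_entropy(grid_pattern(matrix(c(0, 1, 0, 1), 2, 2)))  # 1 bit
#' @export
shannon_entropy <- function(pattern) {
  stopifnot(is_grid_pattern(pattern))
  if (!is_integer_quantized(pattern))
    stop("pattern must be integer-quantized (see quantize())", call. = FALSE)
  sum(vapply(pattern$bands, function(v) {
    p <- tabulate(match(v, unique(c(v))))
    p <- p / sum(p)
    -sum(p * log2(p))
  }, numeric(1)))
}

#' Count bounded integer compositions (microstates of a block)
#'
#' The configurational-entropy measures treat each aggregation block as a
#' macrostate: `d` cells whose values lie in `[lo, hi]` and whose sum `s` is
#' known. `microstate_count()` returns the number of integer `d`-tuples
#' consistent with that macrostate, by inclusion-exclusion over the upper
#' bound:
#' `W = sum_j (-1)^j C(d, j) C(t - j (m+1) + d - 1, d - 1)`
#' with `t = s - d lo` and `m = hi - lo`. Exact for all block sizes used in
#' practice.
#'
#' @param d number of cells in the block.
#' @param s block sum (the macrostate).
#' @param lo,hi per-cell integer bounds.
#' @return the integer microstate count `W`.
#' @examples
#' microstate_count(4, 6, 0, 3)  # 44
#' @export
microstate_count <- function(d, s, lo, hi) {
  stopifnot(d >= 1, hi >= lo)
  t <- s - d * lo
  m <- hi - lo
  if (t < 0 || t > d * m)
    stop("infeasible macrostate: sum ", s, " outside [", d * lo, ", ", d * hi, "]",
         call. = FALSE)
  j <- 0:floor(t / (m + 1))
  sum((-1)^j * choose(d, j) * choose(t - j * (m + 1) + d - 1, d - 1))
}

# log W for one block: d cells in [0, m], sum t. Reflection W(t) = W(dm - t)
# moves the evaluation to the lower tail, where the alternating
# inclusion-exclusion sum has at most d/2 + 1 terms and mild cancellation;
# choose() with a small integer k is a short exact product, so the result
# keeps ~13+ significant digits even for block sums of order 1e5.
log_microstate_W <- function(d, t, m) {
  t <- min(t, d * m - t)
  j <- 0:min(d, t %/% (m + 1))
  w <- sum((-1)^j * choose(d, j) * choose(t - j * (m + 1) + d - 1, d - 1))
  if (!is.finite(w) || w < 1)
    stop("microstate count lost precision (d=", d, ", m=", m, ", t=", t, ")",
         call. = FALSE)
  log(w)
}

# log-microstate total of one aggregation step on an integer array:
# sum over blocks of log W(block sum), bounds [lo, hi] per cell. Evaluated
# once per distinct block sum.
level_log_microstates <- function(a, lambda, lo, hi) {
  d <- lambda^length(dim(a))
  sums <- block_reduce(a, lambda, op = "sum")
  t <- round(as.vector(sums) - d * lo)
  m <- round(hi - lo)
  if (m == 0) {
    if (any(t != 0)) stop("infeasible macrostate in aggregation hierarchy", call. = FALSE)
    return(0)
  }
  if (any(t < 0) || any(t > d * m))
    stop("infeasible macrostate in aggregation hierarchy", call. = FALSE)
  ut <- unique(t)
  lw <- vapply(ut, log_microstate_W, numeric(1), d = d, m = m)
  sum(lw[match(t, ut)])
}

resolve_bounds <- function(band, bounds) {
  if (is.null(bounds)) bounds <- range(band)
  if (any(bounds != round(bounds)))
    stop("microstate bounds must be integers", call. = FALSE)
  bounds
}

#' Relative Boltzmann entropy of an integer gradient
#'
#' One aggregation step: the pattern is cut into `lambda^D` blocks, each
#' block's sum is its macrostate, and
#' `ER = sum_blocks log W(block)` counts (in log) how many fine-grained
#' configurations are consistent with the coarse description. Per-cell
#' bounds default to the observed `[min, max]` of the pattern, making any
#' constant pattern zero-entropy; pass `bounds` explicitly to compare
#' patterns on a common value range (series computations fix the range over
#' the whole sequence).
#'
#' @param pattern an integer-quantized [grid_pattern()], spatial extents
#'   divisible by `lambda`.
#' @param lambda block edge (2 is the standard choice: 2x2 blocks in 2D,
#'   2x2x2 in 3D).
#' @param bounds optional `c(lo, hi)` per-cell integer bounds.
#' @param base logarithm base (default natural; trends are base-invariant).
#' @return `ER` (log-microstates). Multi-band patterns: sum over bands.
#' @examples
#' relative_boltzmann(grid_pattern(matrix(c(0, 2, 1, 3), 2, 2)))  # log(44)
#' @export
relative_boltzmann <- function(pattern, lambda = 2L, bounds = NULL, base = exp(1)) {
  stopifnot(is_grid_pattern(pattern))
  if (!is_integer_quantized(pattern))
    stop("pattern must be integer-quantized (see quantize())", call. = FALSE)
  lambda <- as.integer(lambda)
  total <- 0
  for (b in seq_len(n_bands(pattern))) {
    a <- pattern$bands[[b]]
    bb <- resolve_bounds(a, bounds)
    total <- total + level_log_microstates(a, lambda, bb[1], bb[2])
  }
  total / log(base)
}

#' Absolute Boltzmann entropy of an integer gradient
#'
#' Accumulates relative entropies over a full aggregation hierarchy, down to
#' a single macro-cell. Two hierarchies are provided:
#'
#' * `mode = "size_reducing"` (the classical `EA`): each level replaces a
#'   block by its *sum*, so per-cell bounds grow by the block size `d` at
#'   every level and no rounding is involved;
#' * `mode = "size_preserving"` (`EA'`): the hierarchy mirrors the
#'   renormalization used by the structural-complexity measure — each level
#'   replaces a block by its *mean*, rounded half-up, with bounds held
#'   constant; per-level counting runs on the distinct (effective)
#'   macro-cells.
#'
#' `EA = sum of the per-level relative entropies` in either mode; the
#' per-level values are attached as `attr(, "per_level")`. Patterns whose
#' shortest side is below `lambda` admit no aggregation step and score 0.
#'
#' @inheritParams relative_boltzmann
#' @param mode `"size_reducing"` or `"size_preserving"`.
#' @return `EA` (or `EA'`), with attribute `per_level`.
#' @export
absolute_boltzmann <- function(pattern, lambda = 2L,
                               mode = c("size_reducing", "size_preserving"),
                               bounds = NULL, base = exp(1)) {
  stopifnot(is_grid_pattern(pattern))
  mode <- match.arg(mode)
  if (!is_integer_quantized(pattern))
    stop("pattern must be integer-quantized (see quantize())", call. = FALSE)
  lambda <- as.integer(lambda)
  total_levels <- NULL
  total <- 0
  for (b in seq_len(n_bands(pattern))) {
    a <- pattern$bands[[b]]
    if (min(dim(a)) < lambda) {
      lev <- numeric(0)
    } else {
      N <- max_steps(dim(a), lambda)
      a <- crop_to_divisible(a, lambda, N)
      d <- lambda^length(dim(a))
      bb <- resolve_bounds(a, bounds)
      lo <- bb[1]; hi <- bb[2]
      lev <- numeric(N)
      for (l in seq_len(N)) {
        lev[l] <- level_log_microstates(a, lambda, lo, hi)
        if (mode == "size_reducing") {
          a <- block_reduce(a, lambda, op = "sum")
          lo <- d * lo; hi <- d * hi
        } else {
          a <- round_half_up(block_reduce(a, lambda, op = "mean"))
        }
      }
    }
    total <- total + sum(lev)
    total_levels <- if (is.null(total_levels)) lev else total_levels + lev
  }
  structure(total / log(base), per_level = total_levels / log(base))
}

#' All entropy measures of one pattern
#'
#' Convenience wrapper computing Shannon entropy `ES`, the one-step relative
#' Boltzmann entropy `ER`, and both absolute Boltzmann entropies (`EA`,
#' size-reducing; `EA'`, size-preserving) in one call.
#'
#' @inheritParams relative_boltzmann
#' @return an `entropy_result` list: `ES` (bits), `ER`, `EA`, `EA_prime`,
#'   `per_level` (list with components `EA`, `EA_prime`), `log_base`.
#' @export
entropy_profile <- function(pattern, lambda = 2L, bounds = NULL, base = exp(1)) {
  ea <- absolute_boltzmann(pattern, lambda, "size_reducing", bounds, base)
  eap <- absolute_boltzmann(pattern, lambda, "size_preserving", bounds, base)
  structure(
    list(ES = shannon_entropy(pattern),
         ER = relative_boltzmann(pattern, lambda, bounds, base),
         EA = as.numeric(ea),
         EA_prime = as.numeric(eap),
         per_level = list(EA = attr(ea, "per_level"),
                          EA_prime = attr(eap, "per_level")),
         log_base = base),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> ES = %.6g bits, ER = %.6g, EA = %.6g, EA' = %.6g\n",
              x$ES, x$ER, x$EA, x$EA_prime))
  invisible(x)
}

#' Entropy of a sequence of patterns
#'
#' Computes one entropy measure per element of an ordered sequence. By
#' default each frame uses its own observed min/max as microstate bounds
#' (the same convention as the single-pattern functions, under which a
#' flat frame carries zero configurational entropy); pass a fixed
#' `bounds = c(lo, hi)` to pin a common value range across the sequence —
#' the natural choice when the admissible range is known a priori, e.g.
#' `c(0, 1)` for binary spin images.
#'
#' @param patterns list of integer-quantized [grid_pattern()]s sharing shape
#'   and bands.
#' @param measure `"shannon"`, `"relative"`, `"absolute"` (EA) or
#'   `"absolute_sp"` (EA', size-preserving hierarchy).
#' @param lambda block edge.
#' @param bounds optional fixed `c(lo, hi)`; default: per-frame observed.
#' @param base log base for the Boltzmann measures.
#' @param control ordered control values.
#' @return a [measure_series()].
#' @export
entropy_series <- function(patterns,
                           measure = c("shannon", "relative", "absolute", "absolute_sp"),
                           lambda = 2L, bounds = NULL, base = exp(1), control = NULL) {
  measure <- match.arg(measure)
  check_homogeneous(patterns)
  f <- switch(measure,
    shannon = function(p) shannon_entropy(p),
    relative = function(p) relative_boltzmann(p, lambda, bounds, base),
    absolute = function(p) as.numeric(absolute_boltzmann(p, lambda, "size_reducing", bounds, base)),
    absolute_sp = function(p) as.numeric(absolute_boltzmann(p, lambda, "size_preserving", bounds, base))
  )
  vals <- vapply(patterns, f, numeric(1))
  lab <- switch(measure, shannon = "ES", relative = "ER", absolute = "EA",
                absolute_sp = "EA'")
  measure_series(vals, control = control, label = lab,
                 meta = list(measure = measure, lambda = lambda, bounds = bounds))
}
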