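#' Theoretical maximum number of renormalization steps
#'
#' With blocks of edge `lambda`, a lattice can be block-averaged
#' `N = floor(log_lambda(min spatial extent))` times before a single cell
#' remains along its shortest side. The default truncation of the structural
#' complexity sum is `k <= N - 3`.
#'
#' @param shape integer vector of spatial extents.
#' @param lambda block edge length, integer >= 2.
#' @return integer `N`.
#' @examples
#' max_steps(c(64, 64, 64), 2)   # 6
#' max_steps(c(4096, 4096), 2)   # 12
#' @export
max_steps <- function(shape, lambda = 2L) {
  if (lambda < 2L || lambda != round(lambda))
    stop("lambda must be an integer >= 2", call. = FALSE)
  m <- min(shape)
  if (m < lambda)
    stop("smallest spatial extent (", m, ") is below lambda (", lambda, ")",
         call. = FALSE)
  n <- 0L
  while (lambda^(n + 1L) <= m) n <- n + 1L
  n
}

#' One renormalization-group step: block averaging
#'
#' Replaces each `lambda^D` block by its mean. In `"size_reducing"` mode the
#' block becomes a single cell and the lattice shrinks by `lambda` per axis;
#' in `"size_preserving"` mode every site of the block is overwritten with
#' the block mean, so the lattice keeps its shape but is constant on blocks.
#'
#' @param level a numeric array (one band of a pattern, or a previous level).
#' @param lambda block edge, integer >= 2.
#' @param mode `"size_reducing"` or `"size_preserving"`.
#' @return the next level as a numeric array.
#' @export
block_average <- function(level, lambda = 2L, mode = c("size_reducing", "size_preserving")) {
  mode <- match.arg(mode)
  if (is.null(dim(level)) || length(level) == 0L)
    stop("level must be a non-empty array", call. = FALSE)
  red <- block_reduce(level, as.integer(lambda), op = "mean")
  if (mode == "size_reducing") red else block_replicate(red, as.integer(lambda))
}

#' Build the ladder of coarse-grained representations
#'
#' Computes `S^(0) ... S^(K)` for one band by repeated block averaging.
#' Shapes not divisible by `lambda^K` are cropped to the largest divisible
#' sub-grid anchored at the origin, which keeps the block arithmetic exact
#' (all the simulated inputs in this package are powers of two, so cropping
#' is a no-op for them).
#'
#' @param band a numeric array (2D or 3D).
#' @param lambda block edge, integer >= 2.
#' @param K number of renormalization steps (levels `0..K`).
#' @param mode `"size_reducing"` (levels shrink) or `"size_preserving"`
#'   (levels keep the original shape, constant on `lambda^k` blocks).
#' @return a `renorm_stack`: list with `levels` (list of arrays), `lambda`,
#'   `mode`, `N` (theoretical maximum number of steps), `level_shapes`.
#' @export
renorm_stack <- function(band, lambda = 2L, K,
                         mode = c("size_reducing", "size_preserving")) {
  mode <- match.arg(mode)
  lambda <- as.integer(lambda)
  N <- max_steps(dim(band), lambda)
  if (K > N)
    stop("K = ", K, " exceeds the theoretical maximum N = ", N, call. = FALSE)
  band <- crop_to_divisible(band, lambda, K)
  levels <- vector("list", K + 1L)
  levels[[1L]] <- band
  # iterate on the reduced representation; size-preserving levels replicate
  # it back to the original lattice (blocks of edge lambda^k, constant)
  red <- band
  if (K >= 1L) for (k in seq_len(K)) {
    red <- block_reduce(red, lambda, op = "mean")
    levels[[k + 1L]] <- if (mode == "size_reducing") red
                        else block_replicate(red, lambda^k)
  }
  structure(
    list(levels = levels, lambda = lambda, mode = mode, N = N,
         level_shapes = lapply(levels, dim)),
    class = "renorm_stack"
  )
}

crop_to_divisible <- function(a, lambda, K) {
  d <- dim(a)
  unit <- lambda^K
  newd <- (d %/% unit) * unit
  if (any(newd < 1L))
    stop("shape ", paste(d, collapse = "x"), " too small for ", K,
         " steps with lambda ", lambda, call. = FALSE)
  if (all(newd == d)) return(a)
  if (length(d) == 2L) a[seq_len(newd[1]), seq_len(newd[2]), drop = FALSE]
  else a[seq_len(newd[1]), seq_len(newd[2]), seq_len(newd[3]), drop = FALSE]
}

#' Overlap between two coarse-grained representations
#'
#' `O_{m,n}` is the mean over original-lattice sites of the (per-site)
#' product of representations `m` and `n`, each replicated back to the
#' original lattice. This site-mean form is equivalent to the block-weighted
#' normalization of the reduced-lattice sum. For block-mean renormalization
#' the identity `O_{k+1,k} = O_{k+1,k+1}` holds exactly, because the coarser
#' level is constant on the blocks over which the finer level is averaged.
#'
#' @param stack a [renorm_stack()].
#' @param m,n level indices, `0 <= m, n <= K`.
#' @return the scalar overlap.
#' @export
overlap <- function(stack, m, n) {
  stopifnot(inherits(stack, "renorm_stack"))
  K <- length(stack$levels) - 1L
  if (m < 0L || n < 0L || m > K || n > K)
    stop("level indices must lie in 0..", K, call. = FALSE)
  am <- stack$levels[[m + 1L]]
  an <- stack$levels[[n + 1L]]
  if (stack$mode == "size_reducing") {
    lam <- stack$lambda
    am <- block_replicate(am, lam^m)
    an <- block_replicate(an, lam^n)
  }
  mean(am * an)
}
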