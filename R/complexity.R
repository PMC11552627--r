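#' Multiscale structural complexity
#'
#' Quantifies how much structure a pattern carries across scales. With the
#' block-mean renormalization ladder `S^(0) .. S^(K)` (blocks of edge
#' `lambda`), the per-scale contribution is
#' `C_k = | O_{k+1,k} - (O_{k,k} + O_{k+1,k+1}) / 2 |`,
#' where `O_{m,n}` is the site-mean overlap of two representations (see
#' [overlap()]). `C_k` measures the dissimilarity a pattern loses at the
#' k-th coarse-graining step: patterns that look the same at every scale
#' (constants, pure noise at coarse scales) contribute little, structured
#' patterns much. Three aggregates are in common use: `C_all` (sum over
#' `k >= 0`), `C_ge1` (sum over `k >= 1`, insensitive to pixel-scale noise)
#' and `C_eq0` (the `k = 0` term alone). The sum is truncated at
#' `k_max = N - 3` by default, `N` being the theoretical maximum number of
#' renormalization steps ([max_steps()]).
#'
#' Multi-band patterns are measured band by band and the complexities summed
#' (the convention for color photographs).
#'
#' @param pattern a [grid_pattern()] (2D or 3D, any number of bands).
#' @param lambda renormalization block edge, integer >= 2 (default 2).
#' @param k_max largest `k` entering the sums; `NULL` (default) uses
#'   `N - 3` whenever that keeps at least one `k >= 1` term, i.e.
#'   `min(N - 1, max(1, N - 3))`, so that `C_ge1` stays defined on small
#'   (heavily coarsened) lattices where the truncation would otherwise
#'   leave no scale.
#' @return a `complexity_result`: list with `per_k` (named vector
#'   `C_0..C_kmax`), `C_all`, `C_ge1`, `C_eq0`, `k_max`, `lambda`, and
#'   `overlaps` (matrix of the `O_{m,n}` used; rows/cols indexed `0..K`,
#'   entries away from the diagonal band are `NA`).
#' @examples
#' p <- grid_pattern(matrix(c(0, 2, 1, 3), 2, 2))
#' structural_complexity(p, k_max = 0)$C_eq0  # 0.625
#' @export
structural_complexity <- function(pattern, lambda = 2L, k_max = NULL) {
  stopifnot(is_grid_pattern(pattern))
  lambda <- as.integer(lambda)
  N <- max_steps(grid_shape(pattern), lambda)
  if (is.null(k_max)) k_max <- min(N - 1L, max(1L, N - 3L))
  k_max <- as.integer(k_max)
  if (k_max < 0L) stop("k_max must be >= 0", call. = FALSE)
  K <- k_max + 1L
  if (K > N)
    stop("pattern of shape ", paste(grid_shape(pattern), collapse = "x"),
         " supports at most k_max = ", N - 1L, " at lambda = ", lambda,
         call. = FALSE)
  per_k <- numeric(K)
  ov <- matrix(NA_real_, K + 1L, K + 1L,
               dimnames = list(0:K, 0:K))
  for (b in seq_len(n_bands(pattern))) {
    stack <- renorm_stack(pattern$bands[[b]], lambda, K, mode = "size_reducing")
    # site-mean overlaps: O_{k,k} = mean(S^(k)^2); O_{k+1,k} = O_{k+1,k+1}
    diag_o <- vapply(stack$levels, function(l) mean(l^2), numeric(1))
    for (k in 0:K) {
      ov[k + 1L, k + 1L] <- (if (is.na(ov[k + 1L, k + 1L])) 0 else ov[k + 1L, k + 1L]) +
        diag_o[k + 1L]
      if (k < K) {
        cur <- if (is.na(ov[k + 2L, k + 1L])) 0 else ov[k + 2L, k + 1L]
        ov[k + 2L, k + 1L] <- cur + diag_o[k + 2L]
        ov[k + 1L, k + 2L] <- ov[k + 2L, k + 1L]
      }
    }
    per_k <- per_k + abs(diag_o[2:(K + 1L)] - 0.5 * (diag_o[1:K] + diag_o[2:(K + 1L)]))
  }
  names(per_k) <- paste0("C_", 0:k_max)
  structure(
    list(per_k = per_k,
         C_all = sum(per_k),
         C_ge1 = if (k_max >= 1L) sum(per_k[-1L]) else 0,
         C_eq0 = per_k[[1L]],
         k_max = k_max, lambda = lambda, N = N, overlaps = ov),
    class = "complexity_result"
  )
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity_result> lambda = %d, k_max = %d\n", x$lambda, x$k_max))
  cat(sprintf("  C_all = %.6g   C_ge1 = %.6g   C_eq0 = %.6g\n",
              x$C_all, x$C_ge1, x$C_eq0))
  print(signif(x$per_k, 6))
  invisible(x)
}

#' Structural complexity of a sequence of patterns
#'
#' Applies [structural_complexity()] to each element of an ordered sequence
#' (mixing iterations, temperature steps, ...) and collects one chosen
#' aggregate per element into a [measure_series()].
#'
#' @param patterns a list of [grid_pattern()]s sharing shape and bands.
#' @param variant which aggregate to report: `"ge1"`, `"all"` or `"eq0"`.
#' @param lambda,k_max passed to [structural_complexity()].
#' @param control ordered control values (defaults to `seq_along(patterns)`).
#' @return a [measure_series()].
#' @export
complexity_series <- function(patterns, variant = c("ge1", "all", "eq0"),
                              lambda = 2L, k_max = NULL, control = NULL) {
  variant <- match.arg(variant)
  check_homogeneous(patterns)
  field <- switch(variant, ge1 = "C_ge1", all = "C_all", eq0 = "C_eq0")
  vals <- vapply(patterns, function(p)
    structural_complexity(p, lambda = lambda, k_max = k_max)[[field]], numeric(1))
  measure_series(vals, control = control,
                 label = paste0("C_", sub("ge1", "k>=1", sub("eq0", "k=0", sub("all", "k>=0", variant)))),
                 meta = list(measure = "structural_complexity", variant = variant,
                             lambda = lambda, k_max = k_max))
}

check_homogeneous <- function(patterns) {
  if (length(patterns) == 0L) stop("empty sequence", call. = FALSE)
  shp <- grid_shape(patterns[[1]])
  nb <- n_bands(patterns[[1]])
  for (p in patterns) {
    if (!identical(grid_shape(p), shp) || n_bands(p) != nb)
      stop("sequence elements must share shape and band count", call. = FALSE)
  }
  invisible(TRUE)
}
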