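#' Simulate two-fluid mixing in a closed 3D container
#'
#' A lattice-gas model of blending two ideal fluids ("coffee" and "milk"):
#' a cubic container of `edge^3` voxels starts fully segregated — every
#' voxel in the left half (first axis) holds 1, the right half 0 — and at
#' each iteration every voxel, visited in raster order, exchanges positions
#' with one voxel drawn uniformly from its 26 first-order (Moore) neighbors
#' that lie inside the container. Swaps conserve the composition exactly;
#' the defaults (`edge = 64`, `iterations = 2000`) take the system from full
#' segregation to statistical uniformity.
#'
#' @param edge container edge length in voxels (even, default 64).
#' @param iterations number of full swap sweeps (default 2000).
#' @param seed RNG seed (the simulator owns its generator; R's global RNG
#'   state is untouched).
#' @param export_every snapshot stride: the initial state, every
#'   `export_every`-th iteration, and the final state are returned
#'   (default 25, keeping the default run's memory footprint modest).
#' @return a list with `snapshots` (list of binary 3D [grid_pattern()]s,
#'   `value_range` `[0, 1]`) and `iterations` (integer vector of the
#'   iteration index of each snapshot).
#' @examples
#' run <- simulate_mixing(edge = 8, iterations = 4, seed = 1, export_every = 2)
#' run$iterations
#' @export
simulate_mixing <- function(edge = 64L, iterations = 2000L, seed = 1L,
                            export_every = 25L) {
  edge <- as.integer(edge)
  if (edge < 2L || edge %% 2L != 0L)
    stop("edge must be an even integer >= 2 (left/right halves must exist)",
         call. = FALSE)
  if (iterations < 0L) stop("iterations must be >= 0", call. = FALSE)
  if (export_every < 1L) stop("export_every must be >= 1", call. = FALSE)
  raw <- cpp_simulate_mixing(edge, as.integer(iterations), as.integer(seed),
                             as.integer(export_every))
  snaps <- lapply(raw$snapshots, function(a) grid_pattern(a, value_range = c(0, 1)))
  list(snapshots = snaps, iterations = as.integer(raw$iterations))
}

#' Simulate a 2D Ising temperature sweep
#'
#' Metropolis single-spin-flip Monte Carlo for the classical Ising
#' ferromagnet (nearest-neighbor coupling `J = 1`, no external field,
#' periodic boundaries) on an `L x L` square lattice. The sweep anneals from
#' the lowest temperature upward, reusing the previous configuration, and
#' after `sweeps_equilibrate` full lattice sweeps at each temperature emits
#' the spin configuration as a binary image (spin -1 -> 0, +1 -> 1). The
#' default temperature grid `0, 0.045, ..., 4.5` (in units of `J`) brackets
#' the exactly known critical temperature `T_c = 2/log(1 + sqrt(2)) ~
#' 2.269 J`. `T = 0` is handled as accept-only-energy-decreasing.
#'
#' @param L lattice edge (default 128).
#' @param temperatures ascending non-negative temperature grid in units of
#'   `J` (default `seq(0, 4.5, by = 0.045)`, 101 points).
#' @param sweeps_equilibrate equilibration sweeps per temperature
#'   (default 1000).
#' @param seed RNG seed.
#' @return a list with `temperatures` and `snapshots` (list of binary 2D
#'   [grid_pattern()]s, `value_range` `[0, 1]`).
#' @examples
#' sw <- simulate_ising(L = 16, temperatures = c(0.5, 2.0, 3.5),
#'                      sweeps_equilibrate = 20, seed = 1)
#' length(sw$snapshots)
#' @export
simulate_ising <- function(L = 128L, temperatures = seq(0, 4.5, by = 0.045),
                           sweeps_equilibrate = 1000L, seed = 1L) {
  L <- as.integer(L)
  if (L < 4L) stop("L must be >= 4", call. = FALSE)
  if (any(temperatures < 0)) stop("temperatures must be non-negative", call. = FALSE)
  if (length(temperatures) > 1L && any(diff(temperatures) <= 0))
    stop("temperatures must be strictly ascending", call. = FALSE)
  snaps <- cpp_simulate_ising(L, as.numeric(temperatures),
                              as.integer(sweeps_equilibrate), as.integer(seed))
  snaps <- lapply(snaps, function(m) grid_pattern(m, value_range = c(0, 1)))
  list(temperatures = as.numeric(temperatures), snapshots = snaps)
}

#' Deterministic fixture patterns
#'
#' A small registry of seeded patterns and sequences used throughout the
#' examples and tests:
#'
#' * `"constant"` — a flat 2D pattern (args: `edge = 64`, `value = 5`);
#' * `"checkerboard"` — alternating 0/1 (args: `edge = 64`);
#' * `"random-binary"` — iid Bernoulli(1/2) 0/1 (args: `edge = 64`);
#' * `"half-half"` — the segregated initial mixing state, 3D
#'   (args: `edge = 64`);
#' * `"noise-ramp"` — a sequence of gray images with monotonically
#'   increasing iid noise amplitude on a fixed smooth base
#'   (args: `frames = 6`, `edge = 256`);
#' * `"worked-4x4"` — a fixed integer 4x4 pattern used in worked examples.
#'
#' @param name registry name.
#' @param seed RNG seed for the stochastic fixtures.
#' @param ... size arguments as listed above.
#' @return a [grid_pattern()], or a list of them for `"noise-ramp"`.
#' @export
make_fixture <- function(name, seed = 1L, ...) {
  args <- list(...)
  edge <- args$edge %||% if (identical(name, "noise-ramp")) 256L else 64L
  switch(name,
    "constant" = grid_pattern(matrix(args$value %||% 5, edge, edge)),
    "checkerboard" = {
      idx <- outer(seq_len(edge), seq_len(edge), `+`)
      grid_pattern((idx %% 2) * 1, value_range = c(0, 1))
    },
    "random-binary" = {
      v <- with_local_seed(seed, matrix(sample(c(0, 1), edge * edge, replace = TRUE),
                                        edge, edge))
      grid_pattern(v, value_range = c(0, 1))
    },
    "half-half" = {
      a <- array(0L, dim = c(edge, edge, edge))
      a[seq_len(edge %/% 2), , ] <- 1L
      grid_pattern(a, value_range = c(0, 1))
    },
    "noise-ramp" = {
      frames <- args$frames %||% 6L
      base <- outer(seq_len(edge), seq_len(edge),
                    function(i, j) 96 + 64 * sin(i / 40) * cos(j / 40))
      with_local_seed(seed, lapply(seq_len(frames), function(f) {
        amp <- 8 * (f - 1)
        v <- pmin(255, pmax(0, round(base + amp * runif(edge * edge, -1, 1))))
        dim(v) <- c(edge, edge)
        grid_pattern(v, value_range = c(0, 255))
      }))
    },
    "worked-4x4" = grid_pattern(matrix(c(
      0, 3, 1, 2,
      1, 2, 3, 0,
      2, 0, 1, 3,
      3, 1, 2, 0), 4, 4, byrow = TRUE), value_range = c(0, 3)),
    stop("unknown fixture '", name, "'", call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
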