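test_that("mixing starts fully segregated and conserves composition", {
  init <- simulate_mixing(edge = 64, iterations = 0, seed = 1)
  expect_length(init$snapshots, 1L)
  expect_equal(sum(init$snapshots[[1]]$bands[[1]]), 131072)  # 64^3 / 2
  expect_identical(init$snapshots[[1]]$bands[[1]],
                   make_fixture("half-half", edge = 64)$bands[[1]])

  run <- simulate_mixing(edge = 8, iterations = 20, seed = 2, export_every = 5)
  expect_equal(run$iterations, c(0L, 5L, 10L, 15L, 20L))
  counts <- vapply(run$snapshots, function(s) sum(s$bands[[1]]), numeric(1))
  expect_true(all(counts == 8^3 / 2))
  expect_true(all(vapply(run$snapshots,
                         function(s) all(s$bands[[1]] %in% c(0L, 1L)), logical(1))))
})

test_that("mixing is seed-deterministic", {
  a <- simulate_mixing(edge = 8, iterations = 10, seed = 7, export_every = 10)
  b <- simulate_mixing(edge = 8, iterations = 10, seed = 7, export_every = 10)
  c <- simulate_mixing(edge = 8, iterations = 10, seed = 8, export_every = 10)
  expect_identical(a$snapshots[[2]]$bands[[1]], b$snapshots[[2]]$bands[[1]])
  expect_false(identical(a$snapshots[[2]]$bands[[1]], c$snapshots[[2]]$bands[[1]]))
  expect_error(simulate_mixing(edge = 7), "even")
})

test_that("mixing approaches statistical uniformity", {
  run <- get_mixing_run(1)
  n <- length(run$snapshots)
  octant_chisq <- function(p) {
    a <- p$bands[[1]]; e <- dim(a)[1]; h <- e / 2
    cuts <- list(1:h, (h + 1):e)
    obs <- as.vector(vapply(cuts, function(i)
      vapply(cuts, function(j)
        vapply(cuts, function(k) sum(a[i, j, k]), numeric(1)), numeric(2)), matrix(0, 2, 2)))
    exp_c <- sum(a) / 8
    sum((obs - exp_c)^2 / exp_c)
  }
  chi_first <- octant_chisq(run$snapshots[[1]])
  expect_gt(chi_first, 1e4)                                    # fully segregated
  expect_lt(octant_chisq(run$snapshots[[n]]), 0.01 * chi_first)  # near-uniform

  # a late cross-section looks like a fair coin: ES ~ 1 bit
  sl <- cross_section(run$snapshots[[n]], 32)
  expect_equal(shannon_entropy(sl), 1, tolerance = 0.05)
})

test_that("Ising snapshots behave physically at the temperature extremes", {
  cold <- simulate_ising(L = 32, temperatures = 0.045, sweeps_equilibrate = 50, seed = 1)
  expect_true(all(cold$snapshots[[1]]$bands[[1]] == 1))  # deep ferromagnetic phase

  zero <- simulate_ising(L = 16, temperatures = 0, sweeps_equilibrate = 10, seed = 1)
  expect_true(all(zero$snapshots[[1]]$bands[[1]] == 1))  # T = 0 never raises energy

  hot <- simulate_ising(L = 64, temperatures = c(4.0, 4.5), sweeps_equilibrate = 300,
                        seed = 3)
  m <- 2 * mean(hot$snapshots[[2]]$bands[[1]]) - 1
  expect_lt(abs(m), 0.1)

  rep1 <- simulate_ising(L = 16, temperatures = c(1, 2.5), sweeps_equilibrate = 30, seed = 5)
  rep2 <- simulate_ising(L = 16, temperatures = c(1, 2.5), sweeps_equilibrate = 30, seed = 5)
  expect_identical(rep1$snapshots[[2]]$bands[[1]], rep2$snapshots[[2]]$bands[[1]])
})

test_that("the default temperature grid yields 101 snapshots", {
  sw <- simulate_ising(L = 8, sweeps_equilibrate = 1, seed = 1)
  expect_length(sw$snapshots, 101L)
  expect_equal(sw$temperatures[c(1, 101)], c(0, 4.5))
  expect_error(simulate_ising(L = 2), "L must be")
  expect_error(simulate_ising(L = 16, temperatures = c(2, 1)), "ascending")
})

test_that("magnetization decays across the annealed sweep", {
  sw <- get_ising_sweep(1)
  mag <- vapply(sw$snapshots, function(s) abs(2 * mean(s$bands[[1]]) - 1), numeric(1))
  expect_gt(mag[2], 0.95)                       # ordered well below T_c
  expect_lt(mean(tail(mag, 10)), 0.1)           # disordered well above T_c
  s <- measure_series(mag, control = sw$temperatures)
  expect_equal(classify_trend(s, window = 9)$shape, "downward")
})

test_that("the fixture registry is deterministic and validated", {
  expect_error(make_fixture("nope"), "unknown fixture")
  w <- make_fixture("worked-4x4")
  expect_identical(grid_shape(w), c(4L, 4L))
  expect_identical(w$bands[[1]], make_fixture("worked-4x4")$bands[[1]])

  rb1 <- make_fixture("random-binary", seed = 4)
  rb2 <- make_fixture("random-binary", seed = 4)
  expect_identical(rb1$bands[[1]], rb2$bands[[1]])

  ramp <- make_fixture("noise-ramp", seed = 1, frames = 4, edge = 32)
  expect_length(ramp, 4L)
  amp <- vapply(ramp, function(p) sd(p$bands[[1]]), numeric(1))
  expect_true(all(diff(amp) > 0))
})
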