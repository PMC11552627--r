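test_that("shannon_entropy measures compositional disorder only", {
  expect_equal(shannon_entropy(grid_pattern(matrix(3, 8, 8))), 0)
  half <- make_fixture("half-half", edge = 8)
  expect_equal(shannon_entropy(half), 1)                   # symmetric binary
  four <- grid_pattern(matrix(rep(0:3, each = 4), 4, 4))
  expect_equal(shannon_entropy(four), 2)                   # log2(4)
  # blind to configuration: checkerboard = segregated
  expect_equal(shannon_entropy(make_fixture("checkerboard", edge = 8)), 1)
  expect_error(shannon_entropy(grid_pattern(matrix(0.5, 2, 2))), "integer")
})

test_that("microstate_count matches exhaustive enumeration across block sizes", {
  expect_equal(microstate_count(4, 6, 0, 3), 44)
  for (d in c(4, 8)) {
    for (m in 0:6) {
      tab <- oracle_counts(d, m)
      for (t in 0:(d * m)) {
        expect_equal(microstate_count(d, t + d * 2, lo = 2, hi = 2 + m), tab[t + 1])
      }
    }
  }
  expect_error(microstate_count(4, 3, 1, 2), "infeasible")
  expect_error(microstate_count(4, 13, 0, 3), "infeasible")
})

test_that("microstate counts are reflection-symmetric and peak near the center", {
  for (d in c(4, 8)) {
    m <- 5
    w <- vapply(0:(d * m), function(s) microstate_count(d, s, 0, m), numeric(1))
    expect_equal(w, rev(w))                       # W(s) = W(d(lo+hi) - s)
    expect_equal(which.max(w) - 1, d * m / 2)     # maximal at the midpoint
    expect_equal(w[1], 1)                         # forced tuples at the ends
    expect_equal(w[length(w)], 1)
  }
})

test_that("relative Boltzmann entropy counts log-microstates per block", {
  expect_equal(relative_boltzmann(grid_pattern(matrix(c(0, 2, 1, 3), 2, 2))), log(44))
  expect_equal(relative_boltzmann(grid_pattern(matrix(5, 8, 8))), 0)

  cb <- make_fixture("checkerboard", edge = 8)
  expect_equal(relative_boltzmann(cb), 16 * log(6))  # every 2x2 block sums to 2

  withr::local_seed(21)
  a <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
  expect_equal(relative_boltzmann(grid_pattern(a)), oracle_er_2d(a, min(a), max(a)))

  # base option only rescales
  expect_equal(relative_boltzmann(cb, base = 2), 16 * log2(6))
  expect_error(relative_boltzmann(grid_pattern(matrix(0.5, 2, 2))), "integer")
})

test_that("absolute Boltzmann entropies match brute-force hierarchies", {
  withr::local_seed(31)
  for (rep in 1:10) {
    a <- matrix(sample(0:6, 16, replace = TRUE), 4, 4)
    p <- grid_pattern(a)
    ea <- absolute_boltzmann(p, mode = "size_reducing")
    expect_equal(as.numeric(ea), oracle_ea_4x4(a, min(a), max(a)))
    expect_length(attr(ea, "per_level"), 2L)
    expect_equal(as.numeric(ea), sum(attr(ea, "per_level")))

    eap <- absolute_boltzmann(p, mode = "size_preserving")
    expect_equal(as.numeric(eap), oracle_eap_4x4(a, min(a), max(a)))
  }
})

test_that("entropies are invariant under value translation", {
  withr::local_seed(41)
  a <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
  p0 <- grid_pattern(a)
  p7 <- grid_pattern(a + 7)
  expect_equal(relative_boltzmann(p0), relative_boltzmann(p7))
  expect_equal(as.numeric(absolute_boltzmann(p0)), as.numeric(absolute_boltzmann(p7)))
  expect_equal(as.numeric(absolute_boltzmann(p0, mode = "size_preserving")),
               as.numeric(absolute_boltzmann(p7, mode = "size_preserving")))
})

test_that("degenerate patterns carry zero configurational entropy", {
  one <- grid_pattern(matrix(7, 1, 1))
  expect_equal(as.numeric(absolute_boltzmann(one)), 0)  # no aggregation possible
  const <- grid_pattern(matrix(2, 16, 16))
  expect_equal(relative_boltzmann(const), 0)
  expect_equal(as.numeric(absolute_boltzmann(const)), 0)
  expect_equal(as.numeric(absolute_boltzmann(const, mode = "size_preserving")), 0)
})

test_that("a segregated field has lower EA than a well-mixed one", {
  half <- make_fixture("half-half", edge = 64)
  withr::local_seed(51)
  mixed_vals <- sample(as.vector(half$bands[[1]]))  # same composition, shuffled
  mixed <- grid_pattern(array(mixed_vals, c(64, 64, 64)), value_range = c(0, 1))
  ea_seg <- as.numeric(absolute_boltzmann(half, bounds = c(0, 1)))
  ea_mix <- as.numeric(absolute_boltzmann(mixed, bounds = c(0, 1)))
  expect_lt(ea_seg, ea_mix)
  expect_lt(ea_seg / ea_mix, 0.05)  # segregation leaves only interface microstates
})

test_that("entropy_profile collects all measures consistently", {
  p <- make_fixture("worked-4x4")
  prof <- entropy_profile(p)
  expect_equal(prof$ES, shannon_entropy(p))
  expect_equal(prof$ER, relative_boltzmann(p))
  expect_equal(prof$EA, sum(prof$per_level$EA))
  expect_equal(prof$EA_prime, sum(prof$per_level$EA_prime))
  expect_true(all(c(prof$ES, prof$ER, prof$EA, prof$EA_prime) >= 0))
})

test_that("entropy_series supports fixed and per-frame bounds", {
  frames <- list(grid_pattern(matrix(0, 4, 4), value_range = c(0, 3)),
                 grid_pattern(matrix(c(0, 2, 1, 3), 4, 4), value_range = c(0, 3)))
  s_fixed <- entropy_series(frames, "relative", bounds = c(0, 3))
  expect_equal(s_fixed$values[1], 4 * log(microstate_count(4, 0, 0, 3)))
  s_obs <- entropy_series(frames, "relative")
  expect_equal(s_obs$values[1], 0)  # flat frame, observed bounds collapse
  expect_equal(s_obs$values[2], s_fixed$values[2])
  const_seq <- entropy_series(rep(list(frames[[2]]), 4), "absolute")
  expect_true(all(const_seq$values == const_seq$values[1]))
})
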