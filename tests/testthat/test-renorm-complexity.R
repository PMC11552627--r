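test_that("max_steps counts whole renormalization steps", {
  expect_equal(max_steps(c(64, 64, 64), 2), 6)
  expect_equal(max_steps(c(2, 2), 2), 1)
  expect_equal(max_steps(c(4096, 4096), 2), 12)
  expect_equal(max_steps(c(48, 64), 2), 5)   # limited by the shortest side
  expect_error(max_steps(c(64, 64), 1), "lambda")
  expect_error(max_steps(c(1, 64), 2), "below lambda")
})

test_that("block averaging reduces or overwrites blocks with their mean", {
  const <- matrix(5, 4, 4)
  expect_equal(block_average(const, 2, "size_reducing"), matrix(5, 2, 2))

  a <- matrix(c(0, 2, 1, 3), 2, 2)   # [[0,1],[2,3]] in row terms
  expect_equal(block_average(a, 2, "size_reducing"), matrix(1.5, 1, 1))

  sp <- block_average(matrix(1:16, 4, 4), 2, "size_preserving")
  expect_identical(dim(sp), c(4L, 4L))
  expect_true(all(sp[1:2, 1:2] == mean(matrix(1:16, 4, 4)[1:2, 1:2])))

  f3 <- array(1, c(4, 4, 4))
  expect_identical(dim(block_average(f3, 2, "size_reducing")), c(2L, 2L, 2L))
})

test_that("overlaps match the literal site-sum on the original lattice", {
  a <- matrix(c(0, 2, 1, 3), 2, 2)
  st <- renorm_stack(a, 2, K = 1)
  expect_equal(overlap(st, 0, 0), 3.5)
  expect_equal(overlap(st, 1, 1), 2.25)
  expect_equal(overlap(st, 1, 0), 2.25)

  expect_equal(overlap(renorm_stack(matrix(3, 4, 4), 2, K = 1), 0, 0), 9)

  withr::local_seed(42)
  b <- matrix(runif(64), 8, 8)
  stb <- renorm_stack(b, 2, K = 3)
  for (m in 0:3) for (n in 0:m) {
    expect_equal(overlap(stb, m, n),
                 oracle_overlap_2d(stb$levels[[m + 1]], stb$levels[[n + 1]],
                                   2, m, n, c(8, 8)),
                 tolerance = 1e-12)
  }
  # mean preservation forces O_{k+1,k} = O_{k+1,k+1}
  for (k in 0:2) {
    expect_equal(overlap(stb, k + 1, k), overlap(stb, k + 1, k + 1),
                 tolerance = 1e-12)
  }
})

test_that("size-preserving stacks are block-constant and overlap-equivalent", {
  withr::local_seed(9)
  a <- matrix(rpois(64, 4), 8, 8)
  red <- renorm_stack(a, 2, K = 2, mode = "size_reducing")
  pre <- renorm_stack(a, 2, K = 2, mode = "size_preserving")
  for (k in 1:2) {
    lev <- pre$levels[[k + 1]]
    expect_identical(dim(lev), c(8L, 8L))
    # every lambda^k block is constant at the reduced level's value
    expect_true(all(lev[1:(2^k), 1:(2^k)] == red$levels[[k + 1]][1, 1]))
    expect_equal(overlap(pre, k, k), overlap(red, k, k), tolerance = 1e-12)
  }
})

test_that("structural complexity reproduces worked values", {
  # coarse-graining fixed point: constants carry no structure
  const <- grid_pattern(matrix(7, 16, 16))
  rc <- structural_complexity(const)
  expect_true(all(rc$per_k == 0))
  expect_equal(rc$C_all, 0)

  p <- grid_pattern(matrix(c(0, 2, 1, 3), 2, 2))
  r <- structural_complexity(p, k_max = 0)
  expect_equal(r$C_eq0, abs(2.25 - 0.5 * (3.5 + 2.25)))   # 0.625
  expect_equal(r$C_all, r$C_eq0 + r$C_ge1)

  # iid binary noise: C_0 -> |E[block-mean^2] - p| / 2 = 0.09375 at p = 1/2
  withr::local_seed(5)
  noise <- grid_pattern(matrix(sample(0:1, 256^2, replace = TRUE), 256, 256),
                        value_range = c(0, 1))
  expect_equal(structural_complexity(noise)$C_eq0, 0.09375, tolerance = 0.003 / 0.09375)
})

test_that("C_k equals |O_{k+1,k+1} - O_{k,k}| / 2 for block-mean renormalization", {
  withr::local_seed(11)
  for (rep in 1:20) {
    a <- matrix(runif(32^2), 32, 32)
    r <- structural_complexity(grid_pattern(a), k_max = 2)
    st <- renorm_stack(a, 2, K = 3)
    for (k in 0:2) {
      expect_equal(r$per_k[[k + 1]],
                   0.5 * abs(overlap(st, k + 1, k + 1) - overlap(st, k, k)),
                   tolerance = 1e-12)
    }
    expect_equal(r$C_all, r$C_eq0 + r$C_ge1, tolerance = 1e-12)
    expect_true(all(r$per_k >= 0))
  }
})

test_that("multi-band complexity is the sum of per-band complexities", {
  withr::local_seed(13)
  bands <- lapply(1:3, function(b) matrix(runif(16^2), 16, 16))
  p <- grid_pattern(bands, value_range = c(0, 1))
  total <- structural_complexity(p, k_max = 2)
  per <- lapply(bands, function(v) structural_complexity(grid_pattern(v), k_max = 2))
  expect_equal(total$per_k, Reduce(`+`, lapply(per, `[[`, "per_k")), tolerance = 1e-12)
})

test_that("k_max defaults and limits follow the lattice size", {
  p64 <- grid_pattern(array(0, c(64, 64, 64)))
  expect_equal(structural_complexity(p64)$k_max, 3)  # N = 6 -> N - 3
  p8 <- grid_pattern(array(0, c(8, 8, 8)))
  expect_equal(structural_complexity(p8)$k_max, 1)   # small lattice keeps one k >= 1
  expect_error(structural_complexity(p8, k_max = 5), "at most")
})

test_that("complexity trends agree across moderate block sizes", {
  # block-size sensitivity smoke check on the noise-ramp fixture
  frames <- make_fixture("noise-ramp", seed = 2, frames = 5, edge = 64)
  for (lam in c(2, 4)) {
    s <- complexity_series(frames, "eq0", lambda = lam)
    expect_true(all(is.finite(s$values)))
    expect_equal(classify_trend(s)$shape, "upward")
  }
})
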