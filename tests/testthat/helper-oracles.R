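# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths: counts come from exhaustive
# enumeration (plus one convolution for d = 8), overlaps from a literal
# site-by-site sum on the original lattice.

# Exhaustive table of bounded compositions for d = 4: number of 4-tuples in
# [0, m]^4 with each possible sum t = 0..4m.
oracle_counts_d4 <- function(m) {
  sums <- rowSums(expand.grid(0:m, 0:m, 0:m, 0:m))
  tabulate(sums + 1L, nbins = 4L * m + 1L)
}

# d = 8 built from two independent enumerated halves.
oracle_counts_d8 <- function(m) {
  t4 <- oracle_counts_d4(m)
  n <- length(t4)
  out <- numeric(2L * n - 1L)
  for (i in seq_len(n)) out[i:(i + n - 1L)] <- out[i:(i + n - 1L)] + t4[i] * t4
  out
}

oracle_counts <- function(d, m) {
  switch(as.character(d),
         "4" = oracle_counts_d4(m),
         "8" = oracle_counts_d8(m),
         stop("oracle supports d in {4, 8}"))
}

# Literal overlap: replicate level values by explicit index arithmetic and
# average the per-site product over the original lattice.
oracle_overlap_2d <- function(level_m, level_n, lambda, m, n, shape) {
  tot <- 0
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      im <- (i - 1) %/% lambda^m + 1; jm <- (j - 1) %/% lambda^m + 1
      iN <- (i - 1) %/% lambda^n + 1; jN <- (j - 1) %/% lambda^n + 1
      tot <- tot + level_m[im, jm] * level_n[iN, jN]
    }
  }
  tot / prod(shape)
}

# Brute-force one-step relative entropy of a 2D integer matrix: 2x2 blocks,
# per-cell bounds [lo, hi], W from the enumeration table.
oracle_er_2d <- function(a, lo, hi) {
  m <- hi - lo
  tab <- oracle_counts_d4(m)
  nr <- nrow(a) / 2; nc <- ncol(a) / 2
  tot <- 0
  for (bi in seq_len(nr)) {
    for (bj in seq_len(nc)) {
      blk <- a[(2 * bi - 1):(2 * bi), (2 * bj - 1):(2 * bj)]
      t <- sum(blk) - 4 * lo
      tot <- tot + log(tab[t + 1])
    }
  }
  tot
}

# Brute-force EA of a 4x4 integer matrix (two size-reducing levels).
oracle_ea_4x4 <- function(a, lo, hi) {
  er0 <- oracle_er_2d(a, lo, hi)
  s1 <- matrix(c(sum(a[1:2, 1:2]), sum(a[3:4, 1:2]),
                 sum(a[1:2, 3:4]), sum(a[3:4, 3:4])), 2, 2)
  er1 <- oracle_er_2d(s1, 4 * lo, 4 * hi)
  er0 + er1
}

# Brute-force EA' of a 4x4 integer matrix (two size-preserving levels:
# rounded block means, constant bounds).
oracle_eap_4x4 <- function(a, lo, hi) {
  er0 <- oracle_er_2d(a, lo, hi)
  m1 <- matrix(c(floor(mean(a[1:2, 1:2]) + 0.5), floor(mean(a[3:4, 1:2]) + 0.5),
                 floor(mean(a[1:2, 3:4]) + 0.5), floor(mean(a[3:4, 3:4]) + 0.5)), 2, 2)
  er1 <- oracle_er_2d(m1, lo, hi)
  er0 + er1
}

smooth5 <- function(v) {
  vapply(seq_along(v), function(i) {
    k <- min(2L, i - 1L, length(v) - i)
    mean(v[(i - k):(i + k)])
  }, numeric(1))
}
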