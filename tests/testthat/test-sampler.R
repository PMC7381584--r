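# the integer Patefield core, its enumeration oracle, and the decimal and
# one-dimensional extensions

test_that("enumeration pmf matches brute-force multiple hypergeometric", {
  # P(n11 = k) for margins (2,1)x(2,1): 1/3 at k = 2, 2/3 at k = 1
  tabs <- enumerate_tables(c(2, 1), c(2, 1))
  p <- vapply(tabs, table_probability, numeric(1))
  n11 <- vapply(tabs, function(t) t[1, 1], numeric(1))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p[n11 == 2]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(p[n11 == 1]), 2 / 3, tolerance = 1e-12)
  expect_equal(sum(p * n11), 4 / 3, tolerance = 1e-12)  # r1 c1 / N
})

test_that("sampler hits the enumerated distribution on small margins", {
  set.seed(42)
  n <- 5e4
  # margins (1,1)x(1,1): the two permutation matrices, each w.p. 1/2
  draws <- sample_integer_table(c(1, 1), c(1, 1), n = n)
  frac_diag <- mean(draws[1, 1, ] == 1)
  expect_lt(abs(frac_diag - 0.5), 3 * sqrt(0.25 / n))
  # margins (2,1)x(2,1): E[n11] = 4/3
  draws2 <- sample_integer_table(c(2, 1), c(2, 1), n = n)
  expect_lt(abs(mean(draws2[1, 1, ]) - 4 / 3), 3 * sqrt(0.3 / n))
})

test_that("sampler agrees with stats::r2dtable (independent implementation)", {
  set.seed(7)
  n <- 4e4
  rs <- c(3, 2, 1)
  cs <- c(2, 2, 2)
  mine <- sample_integer_table(rs, cs, n = n)
  ref <- stats::r2dtable(n, rs, cs)
  # compare the full empirical distribution cellwise (means and variances)
  mine_mean <- apply(mine, c(1, 2), mean)
  ref_mean <- Reduce(`+`, ref) / n
  expect_equal(mine_mean, ref_mean, tolerance = 0.05)
  expect_equal(mean(vapply(seq_len(n), function(i) mine[1, 1, i]^2,
                           numeric(1))),
               mean(vapply(ref, function(t) t[1, 1]^2, numeric(1))),
               tolerance = 0.08)
})

test_that("degenerate margins force the table", {
  expect_equal(sample_integer_table(c(5, 0), c(2, 3)),
               matrix(c(2, 0, 3, 0), 2, 2))
  expect_error(sample_integer_table(c(2, 1), c(1, 1)), "equal sums")
})

test_that("integer replicates conserve marginals exactly", {
  set.seed(1)
  for (i in 1:20) {
    rs <- rpois(3, 8)
    cs <- as.vector(rmultinom(1, sum(rs), c(0.2, 0.5, 0.3)))
    reps <- sample_integer_table(rs, cs, n = 50)
    expect_true(all(apply(reps, 3, rowSums) == rs))
    expect_true(all(apply(reps, 3, colSums) == cs))
  }
})

test_that("decimal sampler discretizes margins to 1/g and conserves them", {
  set.seed(3)
  m <- sample_decimal_table(c(0.12, 0.08), c(0.15, 0.05), g = 1e3)
  expect_equal(rowSums(m), c(0.12, 0.08), tolerance = 1e-9)
  expect_equal(colSums(m), c(0.15, 0.05), tolerance = 1e-9)

  reps <- sample_decimal_table(c(0.137, 0.261), c(0.19, 0.1, 0.108),
                               g = 1e4, n = 500)
  dev <- apply(reps, 3, function(x) {
    max(abs(rowSums(x) - c(0.137, 0.261)),
        abs(colSums(x) - c(0.19, 0.1, 0.108)))
  })
  expect_true(all(dev <= 1e-4 + 1e-12))

  # a zero column stays zero in every replicate
  z <- sample_decimal_table(c(0.1, 0.1), c(0.2, 0), g = 1e3, n = 100)
  expect_true(all(z[, 2, ] == 0))
})

test_that("decimal cell means approach r_i c_j / N (g large)", {
  set.seed(11)
  rs <- c(0.31, 0.14)
  cs <- c(0.2, 0.05, 0.2)
  n <- 2e4
  reps <- sample_decimal_table(rs, cs, g = 1e4, n = n)
  expected <- outer(rs, cs) / sum(rs)
  for (i in 1:2) for (j in 1:3) {
    mc_se <- sd(reps[i, j, ]) / sqrt(n)
    expect_lt(abs(mean(reps[i, j, ]) - expected[i, j]), 3 * mc_se + 1e-4)
  }
})

test_that("granularity auto-escalates when a margin would vanish", {
  # 1e-5 rounds to zero at g = 100 but not at g = 1e6
  m <- sample_decimal_table(c(1e-5, 0.5 - 1e-5), c(0.25, 0.25), g = 100)
  expect_gt(sum(m[1, ]), 0 - 1e-12)
  expect_equal(sum(m), 0.5, tolerance = 1e-6)
})

test_that("one-dimensional null redistributes the row total uniformly", {
  expect_equal(sample_one_dim(0, 4), matrix(0, 4, 1))
  expect_equal(as.vector(sample_one_dim(2.5, 1)), 2.5)
  expect_error(sample_one_dim(1, 0), "n_cells")
  set.seed(5)
  n <- 1e4
  reps <- sample_one_dim(1.0, 4, g = 1e4, n = n)
  expect_equal(colSums(reps), rep(1, n), tolerance = 1e-9)
  for (i in 1:4) {
    mc_se <- sd(reps[i, ]) / sqrt(n)
    expect_lt(abs(mean(reps[i, ]) - 0.25), 3 * mc_se)
  }
})

test_that("sampling is deterministic under a fixed seed", {
  set.seed(99)
  a <- sample_decimal_table(c(0.3, 0.2), c(0.25, 0.25), n = 10)
  set.seed(99)
  b <- sample_decimal_table(c(0.3, 0.2), c(0.25, 0.25), n = 10)
  expect_identical(a, b)
})

test_that("largest-remainder rounding preserves totals and proximity", {
  set.seed(8)
  for (i in 1:25) {
    x <- runif(6) * 10
    total <- round(sum(x))
    r <- largest_remainder_round(x, total)
    expect_equal(sum(r), total)
    expect_true(all(abs(r - x) < 1 + 1e-9))
  }
})
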