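# independent enumeration oracle for the sign-flip permutation test
perm_oracle_p <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  means <- abs(signs %*% d) / n
  mean(means >= abs(mean(d)) - 1e-12)
}

# independent enumeration oracle for the Mann-Whitney U test
mw_oracle_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  combs <- utils::combn(n + m, n)
  u <- apply(combs, 2, function(ix) sum(r[ix])) - n * (n + 1) / 2
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mean(abs(u - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-12)
}

test_that("paired permutation test enumerates sign flips exactly", {
  expect_equal(paired_permutation_test(c(1, 1, 1))$p_value, 0.25)
  z <- paired_permutation_test(c(0, 0, 0))
  expect_equal(z$p_value, 1.0)
  expect_true(z$degenerate)

  set.seed(3)
  for (rep in 1:10) {
    d <- rnorm(sample(4:10, 1))
    r <- paired_permutation_test(d)
    expect_true(r$exact)
    expect_equal(r$p_value, perm_oracle_p(d), tolerance = 1e-12)
    # exact two-sided p has granularity 1/2^(n-1) and minimum 2/2^n
    n <- length(d)
    expect_gte(r$p_value, 2 / 2^n - 1e-12)
    expect_lt(abs(r$p_value * 2^n - round(r$p_value * 2^n)), 1e-9)
  }
})

test_that("permutation p is scale invariant, flip symmetric, and the Monte
           Carlo mode agrees with enumeration", {
  set.seed(9)
  d <- rnorm(10, 0.3)
  p <- paired_permutation_test(d)$p_value
  expect_equal(paired_permutation_test(5 * d)$p_value, p, tolerance = 1e-12)
  expect_equal(paired_permutation_test(-d)$p_value, p, tolerance = 1e-12)

  pm <- paired_permutation_test(d, reps = 4000, seed = 11, exact_max_n = 5)
  expect_false(pm$exact)
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(pm$p_value - p), 3 * se + 1 / 4000)
})

test_that("Mann-Whitney U matches enumeration, wilcox.test and its
           approximation", {
  r <- mann_whitney_u(c(3, 4), c(1, 2))
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)

  set.seed(13)
  for (rep in 1:10) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_oracle_p(x, y),
                 tolerance = 1e-12)
    # cross-check against the standard implementation (tie-free, exact)
    expect_equal(mann_whitney_u(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    # tie-aware enumeration
    xt <- sample(1:3, n, replace = TRUE); yt <- sample(1:3, m, replace = TRUE)
    expect_equal(mann_whitney_u(xt, yt)$p_value, mw_oracle_p(xt, yt),
                 tolerance = 1e-12)
  }

  # normal approximation with continuity correction tracks the exact p
  set.seed(14)
  dmax <- max(replicate(40, {
    x <- rnorm(8); y <- rnorm(8)
    abs(mann_whitney_u(x, y, exact_max = 16)$p_value -
        mann_whitney_u(x, y, exact_max = 0)$p_value)
  }))
  expect_lt(dmax, 0.02)
})

test_that("bootstrap mean-difference CI behaves on known inputs", {
  r <- paired_mean_difference_ci(c(1, 2, 3))
  expect_equal(r$effect_size, 2.0)
  expect_true(r$ci_low <= 2 && 2 <= r$ci_high)

  const <- paired_mean_difference_ci(rep(0.5, 6))
  expect_equal(const$ci_low, 0.5)
  expect_equal(const$ci_high, 0.5)
  expect_true(const$degenerate)

  set.seed(15)
  d <- rnorm(25, 0.05, 0.1)
  r2 <- paired_mean_difference_ci(d, reps = 3000, seed = 2)
  expect_true(r2$ci_low <= mean(d) && mean(d) <= r2$ci_high)
  expect_match(r2$method, "bootstrap")
  # same seed reproduces the interval
  r3 <- paired_mean_difference_ci(d, reps = 3000, seed = 2)
  expect_identical(r2$ci_low, r3$ci_low)
})

test_that("linear regression R^2 matches the correlation identity", {
  x <- 1:10
  exact <- suppressWarnings(linregress_r2(x, 2 * x + 1))
  expect_equal(exact$r2, 1.0, tolerance = 1e-12)
  expect_equal(exact$slope, 2, tolerance = 1e-12)

  # orthogonal response: zero covariance gives r2 = 0
  xo <- c(-1, 0, 1); yo <- c(1, -2, 1)
  expect_equal(linregress_r2(xo, yo)$r2, 0, tolerance = 1e-12)

  set.seed(17)
  xr <- rnorm(50); yr <- 0.4 * xr + rnorm(50)
  expect_equal(linregress_r2(xr, yr)$r2, cor(xr, yr)^2, tolerance = 1e-12)

  flaty <- linregress_r2(xr, rep(2, 50))
  expect_equal(flaty$r2, 0)
  expect_true(flaty$degenerate)
  expect_error(linregress_r2(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("stats_table collects results in the summary layout", {
  tab <- stats_table(list(
    a_vs_b = mann_whitney_u(c(3, 4), c(1, 2)),
    paired = paired_permutation_test(c(1, 1, 1))))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("comparison", "test", "p_value", "effect_size",
                    "ci_low", "ci_high", "n", "method") %in% names(tab)))
  expect_match(tab$method[1], "exact")
})
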