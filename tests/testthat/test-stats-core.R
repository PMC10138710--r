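test_that("bray_curtis matches hand-computed values and handles edge cases", {
  d <- bray_curtis(rbind(a = c(0.2, 0.8), b = c(0.4, 0.6)))
  expect_equal(d["a", "b"], 0.2)
  expect_equal(d["a", "a"], 0)
  d2 <- bray_curtis(rbind(x = c(1, 0, 0), y = c(0, 2, 3)))
  expect_equal(d2["x", "y"], 1)  # disjoint supports
  d3 <- bray_curtis(rbind(x = c(0, 0), y = c(0, 0), z = c(1, 1)))
  expect_true(is.na(d3["x", "y"]))  # undefined for an all-zero pair
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("fisher_exact equals hypergeometric enumeration for all totals <= 20", {
  for (n in c(5, 10, 16, 20)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      tab <- matrix(c(a, cc, b, n - a - b - cc), 2)
      expect_equal(fisher_exact(tab), fisher_enum(tab), tolerance = 1e-10)
    }
  }
  # Fisher on a cohort-style 4/13 vs 11/16 sex split lands near 0.07
  expect_equal(round(fisher_exact(matrix(c(4, 11, 9, 5), 2)), 2), 0.07)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("bh_fdr reproduces the step-up computation and its monotonicity", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)      # single test: q = p
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(1)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), seq_len(50))  # q respects the p order
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank tests match exact enumeration and behave at the extremes", {
  set.seed(2)
  for (r in 1:5) {
    x <- rnorm(5); y <- rnorm(5) + r / 4
    expect_equal(rank_tests(x, y)$p_value, mw_enum(x, y), tolerance = 1e-10)
  }
  sep <- rank_tests(1:10, 11:20)
  expect_equal(unname(sep$statistic), 0)  # complete separation: U = 0
  expect_lt(sep$p_value, 2e-4)
  same <- rank_tests(c(1, 5, 9, 13), c(1, 5, 9, 13))
  expect_gt(same$p_value, 0.9)
  paired <- rank_tests(c(3, 5, 1, 7, 2), c(1, 2, 0, 3, 1), paired = TRUE)
  expect_lt(paired$p_value, 0.1)
  expect_error(rank_tests(1:3, 1:3, paired = TRUE), "zero")
  expect_error(rank_tests(1:4, 1:3, paired = TRUE), "equal length")
})

test_that("kruskal_wallis separates distinct groups and rejects bad input", {
  strong <- kruskal_wallis(list(1:10, 21:30, 41:50))
  expect_lt(strong$p_value, 1e-5)
  expect_equal(unname(strong$df), 2)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("pcoa reconstructs planted Euclidean configurations", {
  pts <- cbind(c(0, 3, 0, 5), c(0, 0, 4, 5))
  d <- as.matrix(dist(pts))
  fit <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(dist(fit$coordinates)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  # equilateral triangle: two equal positive eigenvalues
  deq <- matrix(1, 3, 3); diag(deq) <- 0
  eq <- pcoa(deq, n_axes = 2)
  pos <- eq$eigenvalues[eq$eigenvalues > 1e-8]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-8)
  # duplicated points coincide
  ddup <- as.matrix(dist(rbind(c(0, 0), c(0, 0), c(1, 0))))
  co <- pcoa(ddup, n_axes = 1)$coordinates
  expect_equal(co[1, ], co[2, ], tolerance = 1e-10)
  expect_error(pcoa(d, n_axes = 4), "n - 1")
})

test_that("permanova partitions distances sensibly and is permutation-exactly bounded", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
  d <- as.matrix(dist(x))
  g <- rep(1:2, each = 10)
  pm <- permanova(d, g, n_perm = 199, seed = 1)
  expect_equal(pm$p_value, 1 / 200)  # extreme separation hits the floor
  expect_gt(pm$r_squared, 0.5)
  # duplicating every sample leaves R2 unchanged
  d2 <- as.matrix(dist(x[rep(1:20, 2), ]))
  pm2 <- permanova(d2, rep(g, 2), n_perm = 99, seed = 1)
  expect_equal(pm2$r_squared, pm$r_squared, tolerance = 1e-9)
  expect_error(permanova(d, rep(1, 20)), "2 groups")
  expect_error(permanova(d, c(1, rep(2, 19)), n_perm = 99), ">= 2 samples")
})

test_that("robust_linreg resists outliers and matches OLS on clean data", {
  set.seed(4)
  x <- cbind(1, rnorm(50))
  y <- 2 + 3 * x[, 2]
  expect_equal(unname(robust_linreg(x, y)$coefficients), c(2, 3),
               tolerance = 1e-6)
  y2 <- 2 + 3 * x[, 2] + rnorm(50, 0, 0.5)
  expect_equal(unname(robust_linreg(x, y2)$coefficients),
               unname(coef(lm(y2 ~ x[, 2]))), tolerance = 1e-2)
  # one gross outlier at the highest-leverage point
  y3 <- y2
  lev <- which.max(abs(x[, 2]))
  y3[lev] <- 100
  rob_err <- abs(robust_linreg(x, y3)$coefficients[2] - 3)
  ols_err <- abs(coef(lm(y3 ~ x[, 2]))[2] - 3)
  expect_lt(rob_err, ols_err)
  expect_error(robust_linreg(cbind(1, 1:5, 2 * (1:5)), rnorm(5)), "rank")
})

test_that("adjusted_rand_index agrees with the mclust reference implementation", {
  set.seed(5)
  for (r in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})
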